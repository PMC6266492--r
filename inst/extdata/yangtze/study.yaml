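# Study metadata for the 2017 item-level account.
# population is a calibrated value (not printed in the source tables): it is
# the resident population solved from the printed (total, per-capita) pairs
# of the 2017 account; any value in (43,344,246, 43,344,378] reproduces every
# printed 4-decimal per-capita and equivalence-area cell.
year: 2017
population: 43344300
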