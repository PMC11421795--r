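TOP	toy fixture set	gene05	gene19	gene17	gene03	gene14	gene18
BOTTOM	toy fixture set	gene09	gene07	gene11	gene04	gene12	gene15
MIXED	toy fixture set	gene09	gene12	gene01	gene10	gene17
RANDOM	toy fixture set	gene08	gene02	gene18	gene05	gene10	gene07	gene03
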