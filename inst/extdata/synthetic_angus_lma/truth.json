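{"sigma2_t":[53.98,53.98,53.98],"sigma2_c":[124.13,124.13,124.13],"sigma2_a":16.87,"sigma2_e":[35.06,35.06,35.06],"G0":{},"mu":[78.2,78.2,78.2],"seed":60930}
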