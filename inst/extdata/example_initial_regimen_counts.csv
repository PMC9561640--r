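regimen,n
ARB,190
CCB,167
BB,36
ACEi,5
DU,3
ARB+CCB,99
ARB+DU,28
ARB+BB,22
ARB+BB+CCB,19
OTHER_COMBINATIONS,67
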