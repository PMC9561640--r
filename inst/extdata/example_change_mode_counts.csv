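regimen,DOSE_INCREASED,DOSE_REDUCED,MEDICATION_ADDED,MEDICATION_REMOVED,CHANGED_WITHIN_CLASS,CHANGED_TO_DIFFERENT_CLASS
CCB,6,4,101,0,14,27
ARB,23,13,46,0,31,30
BB,3,4,11,0,5,7
DU,1,0,3,0,0,1
ACEi,2,0,1,0,0,1
ARB+CCB,7,17,13,19,17,26
ARB+DU,4,0,8,12,2,10
ARB+BB,5,1,4,10,2,13
BB+CCB,2,2,1,7,5,10
CCB+DU,1,1,0,5,2,1
BB+DU,0,1,3,1,1,1
ACEi+BB,3,0,0,2,0,0
ARB+BB+CCB,2,4,2,15,7,10
ARB+CCB+DU,3,3,3,15,1,7
ARB+BB+CCB+DU,0,5,0,6,6,2
ARB+BB+DU,0,0,2,5,0,3
ACEi+BB+DU,0,0,0,3,0,2
OTHER_COMBINATIONS,1,1,2,15,0,7
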