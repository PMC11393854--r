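patient_id,stage,age_years,sex,iss,r_iss,best_response,pfs_months,pfs_event,os_months,os_event
AIRC19_001,SMM,,,,,,38,FALSE,38,FALSE
AIRC19_013,SMM,,,,,,34,TRUE,34,FALSE
AIRC19_021,SMM,,,,,,26,FALSE,26,FALSE
AIRC19_051,SMM,,,,,,19,TRUE,19,FALSE
AIRC19_054,SMM,,,,,,2,TRUE,2,FALSE
AIRC19_055,SMM,,,,,,16,TRUE,16,FALSE
AIRC19_075,SMM,,,,,,16,FALSE,16,FALSE
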