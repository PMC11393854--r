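patient_id,time_months,phase,cmmc_count,beta2m,albumin,calcium,crp,ldh,m_protein,kappa_lambda_ratio,total_protein,bm_pc_percent
AIRC19_001,17,untreated_followup,22,,,,,,,,,
AIRC19_001,21,untreated_followup,2,,,,,,,,,
AIRC19_001,38,untreated_followup,52,,,,,,,,,
AIRC19_013,12,untreated_followup,24,,,,,,,,,
AIRC19_013,23,untreated_followup,100,,,,,,,,,
AIRC19_013,27,progression,0,,,,,,,,,
AIRC19_021,2,untreated_followup,52,,,,,,,,,
AIRC19_021,7,untreated_followup,159,,,,,,,,,
AIRC19_021,13,untreated_followup,49,,,,,,,,,
AIRC19_021,26,untreated_followup,138,,,,,,,,,
AIRC19_051,1,untreated_followup,976,,,,,,,,,
AIRC19_051,4,progression,960,,,,,,,,,
AIRC19_054,1,untreated_followup,327,,,,,,,,,
AIRC19_054,4,progression,38,,,,,,,,,
AIRC19_055,4,untreated_followup,2463,,,,,,,,,
AIRC19_055,11,untreated_followup,390,,,,,,,,,
AIRC19_055,14,progression,619,,,,,,,,,
AIRC19_075,8,untreated_followup,344,,,,,,,,,
AIRC19_075,12,untreated_followup,656,,,,,,,,,
AIRC19_075,16,untreated_followup,371,,,,,,,,,
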