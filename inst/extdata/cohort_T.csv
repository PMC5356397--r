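id,sire,dam,sex,diagnosed,age_years,alive,litter_id
ABE,,,male,FALSE,10,FALSE,
LAVE,,,female,FALSE,10,FALSE,
VIK,,,male,FALSE,10.5,FALSE,
COCA,,,female,FALSE,9.5,FALSE,
DENA,,,female,FALSE,11,FALSE,
T5S,,,male,FALSE,9,FALSE,
T5D,,,female,FALSE,10,FALSE,
T3S,,,male,FALSE,10,FALSE,
T3D,,,female,TRUE,8,FALSE,
SAM,,,male,FALSE,9.5,FALSE,
T6D,,,female,TRUE,7,FALSE,
T7S,,,male,FALSE,9,FALSE,
T7D,,,female,TRUE,7.5,FALSE,
T4D,,,female,FALSE,5,FALSE,
T1M1,ABE,LAVE,male,TRUE,7,FALSE,T1
T1F1,ABE,LAVE,female,FALSE,9,FALSE,T1
T1M2,ABE,LAVE,male,FALSE,10,FALSE,T1
T1F2,ABE,LAVE,female,FALSE,9.5,FALSE,T1
T2M1,VIK,COCA,male,TRUE,6.5,FALSE,T2
T2F1,VIK,COCA,female,TRUE,7,FALSE,T2
T2F2,VIK,COCA,female,FALSE,9,FALSE,T2
T2M2,VIK,COCA,male,FALSE,10,FALSE,T2
T2F3,VIK,COCA,female,FALSE,11,FALSE,T2
T3M1,T3S,T3D,male,TRUE,6,FALSE,T3
T3F1,T3S,T3D,female,TRUE,7,FALSE,T3
T3M2,T3S,T3D,male,TRUE,7.5,FALSE,T3
T3F2,T3S,T3D,female,TRUE,8,FALSE,T3
T3M3,T3S,T3D,male,TRUE,6.5,FALSE,T3
T3F3,T3S,T3D,female,TRUE,7,FALSE,T3
T3M4,T3S,T3D,male,TRUE,8,FALSE,T3
RIF,T3S,T3D,male,FALSE,10,FALSE,T3
T3F4,T3S,T3D,female,FALSE,9,FALSE,T3
T4M1,RIF,T4D,male,TRUE,6,FALSE,T4
T4F1,RIF,T4D,female,FALSE,9,FALSE,T4
T4M2,RIF,T4D,male,FALSE,10,FALSE,T4
T5F1,T5S,T5D,female,FALSE,9,FALSE,T5
T5M1,T5S,T5D,male,FALSE,10,FALSE,T5
T5F2,T5S,T5D,female,FALSE,9.5,FALSE,T5
T5M2,T5S,T5D,male,FALSE,11,FALSE,T5
T5F3,T5S,T5D,female,FALSE,10.5,FALSE,T5
T5M3,T5S,T5D,male,FALSE,9,FALSE,T5
T6M1,SAM,T6D,male,TRUE,6,FALSE,T6
T6F1,SAM,T6D,female,TRUE,7,FALSE,T6
T6M2,SAM,T6D,male,TRUE,7.5,FALSE,T6
T6F2,SAM,T6D,female,TRUE,8,FALSE,T6
T6M3,SAM,T6D,male,TRUE,6.5,FALSE,T6
T6F3,SAM,T6D,female,TRUE,7,FALSE,T6
T6M4,SAM,T6D,male,TRUE,5.5,FALSE,T6
T6F4,SAM,T6D,female,FALSE,9,FALSE,T6
T6M5,SAM,T6D,male,FALSE,10,FALSE,T6
T6F5,SAM,T6D,female,FALSE,9.5,FALSE,T6
T7M1,T7S,T7D,male,TRUE,6,FALSE,T7
T7F1,T7S,T7D,female,TRUE,7,FALSE,T7
T7M2,T7S,T7D,male,TRUE,8,FALSE,T7
T7F2,T7S,T7D,female,TRUE,7.5,FALSE,T7
T8M1,VIK,DENA,male,TRUE,7,FALSE,T8
T8F1,VIK,DENA,female,TRUE,6.5,FALSE,T8
T8F2,VIK,DENA,female,FALSE,9,FALSE,T8
T8M2,VIK,DENA,male,FALSE,10,FALSE,T8
T8F3,VIK,DENA,female,FALSE,9.5,FALSE,T8
T8M3,VIK,DENA,male,FALSE,11,FALSE,T8
T8F4,VIK,DENA,female,FALSE,10,FALSE,T8
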