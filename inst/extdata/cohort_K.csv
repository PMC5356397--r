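id,sire,dam,sex,diagnosed,age_years,alive,litter_id
TAL,,,male,FALSE,10,FALSE,
OAN,,,male,FALSE,10,FALSE,
ART,,,male,FALSE,10.5,FALSE,
SON,,,male,FALSE,6,FALSE,
KELL,,,female,FALSE,9.5,FALSE,
PEN,,,male,FALSE,12,FALSE,
LIUM,,,female,TRUE,10,FALSE,
SPIG,,,female,FALSE,13,FALSE,
AMP,,,male,FALSE,6,FALSE,
MYCK,,,female,FALSE,9.5,FALSE,
K2S,,,male,FALSE,9,FALSE,
K2D,,,female,TRUE,8,FALSE,
K3S,,,male,FALSE,10,FALSE,
K3D,,,female,TRUE,7.5,FALSE,
K4D,,,female,TRUE,8,FALSE,
K5D,,,female,TRUE,9,FALSE,
K6D,,,female,TRUE,7,FALSE,
K9D,,,female,TRUE,8,FALSE,
K12S,,,male,FALSE,10,FALSE,
K12D,,,female,FALSE,11,FALSE,
LANG,AMP,MYCK,female,FALSE,12,FALSE,K8
CRY,SON,KELL,male,FALSE,10,FALSE,K11
K1M1,TAL,LANG,male,TRUE,7,FALSE,K1
K1F1,TAL,LANG,female,TRUE,8,FALSE,K1
K1M2,TAL,LANG,male,FALSE,9,FALSE,K1
K1F2,TAL,LANG,female,FALSE,10,FALSE,K1
K1M3,TAL,LANG,male,FALSE,9.5,FALSE,K1
K1F3,TAL,LANG,female,FALSE,11,FALSE,K1
K2M1,K2S,K2D,male,TRUE,6.5,FALSE,K2
K3M1,K3S,K3D,male,TRUE,7,FALSE,K3
K3F1,K3S,K3D,female,TRUE,7.5,FALSE,K3
K3F2,K3S,K3D,female,FALSE,9,FALSE,K3
K4M1,OAN,K4D,male,TRUE,6,FALSE,K4
K4F1,OAN,K4D,female,TRUE,8,FALSE,K4
K4M2,OAN,K4D,male,FALSE,10,FALSE,K4
K4F2,OAN,K4D,female,FALSE,9,FALSE,K4
K5M1,OAN,K5D,male,FALSE,9,FALSE,K5
K6F1,CRY,K6D,female,TRUE,7,FALSE,K6
K6M1,CRY,K6D,male,FALSE,9,FALSE,K6
K6M2,CRY,K6D,male,FALSE,10,FALSE,K6
K6F2,CRY,K6D,female,FALSE,9.5,FALSE,K6
K7F1,CRY,SPIG,female,FALSE,9,FALSE,K7
K8M1,AMP,MYCK,male,TRUE,7,FALSE,K8
K8F1,AMP,MYCK,female,TRUE,8,FALSE,K8
K8M2,AMP,MYCK,male,FALSE,9,FALSE,K8
K8F2,AMP,MYCK,female,FALSE,10,FALSE,K8
K8M3,AMP,MYCK,male,FALSE,9.5,FALSE,K8
K8F3,AMP,MYCK,female,FALSE,11,FALSE,K8
K8M4,AMP,MYCK,male,FALSE,10.5,FALSE,K8
K9M1,ART,K9D,male,TRUE,7,FALSE,K9
K9F1,ART,K9D,female,TRUE,6.5,FALSE,K9
K9M2,ART,K9D,male,FALSE,9,FALSE,K9
K9F2,ART,K9D,female,FALSE,10,FALSE,K9
K9M3,ART,K9D,male,FALSE,9.5,FALSE,K9
K10F1,PEN,LIUM,female,FALSE,9,FALSE,K10
K10M1,PEN,LIUM,male,FALSE,10,FALSE,K10
K10F2,PEN,LIUM,female,FALSE,9.5,FALSE,K10
K11M1,SON,KELL,male,TRUE,6,FALSE,K11
K11F1,SON,KELL,female,TRUE,7,FALSE,K11
K11M2,SON,KELL,male,TRUE,7.5,FALSE,K11
K11F2,SON,KELL,female,TRUE,8,FALSE,K11
K11M3,SON,KELL,male,TRUE,6.5,FALSE,K11
K11F3,SON,KELL,female,FALSE,9,FALSE,K11
K11M4,SON,KELL,male,FALSE,10,FALSE,K11
K11F4,SON,KELL,female,FALSE,9.5,FALSE,K11
K12F1,K12S,K12D,female,FALSE,9,FALSE,K12
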