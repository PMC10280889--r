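patient_id,icd10_code,year
P001,I21.0,2015
P002,Z03.8,2015
P003,I48,2015
P004,A09.0,2016
P005,B15.9,2016
P006,S72.1,2016
P007,Z76.5,2017
P008,I21.1,2017
P009,G40.3,2017
P010,C50.1,2018
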