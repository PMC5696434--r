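synthetic two-population sample (150 y divergence)
A112
A130
C4
C114
D102
R9
Pop
isolated_31 ,  001001 001002 001001 001003 001001 001001
isolated_32 ,  001001 001002 006001 001001 001001 001001
isolated_33 ,  001001 001002 001001 001003 001001 001001
isolated_34 ,  001001 001001 006005 001003 001001 001001
isolated_35 ,  001001 001002 005005 003003 001001 001001
isolated_36 ,  001001 008001 005003 003001 001001 001001
isolated_37 ,  001001 002008 001001 001003 001001 001001
isolated_38 ,  002001 008001 005001 003003 001001 001001
isolated_39 ,  002001 008001 003005 003003 001001 001001
isolated_40 ,  001001 001001 001005 001003 001001 001001
isolated_41 ,  001005 001001 005006 001003 001001 001001
isolated_42 ,  001005 008001 006005 001003 001001 001001
isolated_43 ,  002005 001001 006005 001003 001001 001001
isolated_44 ,  002005 008001 005006 001001 001001 001001
isolated_45 ,  005001 001001 001006 003001 001001 001001
isolated_46 ,  001001 001001 001003 003003 001001 001001
isolated_47 ,  001002 008001 005005 003003 001001 001001
isolated_48 ,  001001 001001 006006 001001 001001 001001
isolated_49 ,  001001 008001 006005 001003 001001 001001
isolated_50 ,  001001 001002 001001 001003 001001 001001
isolated_51 ,  001001 001002 006001 001001 001001 001001
isolated_52 ,  001001 001003 001005 003003 001001 001001
isolated_53 ,  001001 001001 005001 001003 001001 001001
isolated_54 ,  001001 008002 006001 001001 001001 001001
isolated_55 ,  001001 002008 001005 001003 001001 001001
isolated_56 ,  001001 001001 005006 003001 001001 001001
isolated_57 ,  001001 001002 001006 003001 001001 001001
isolated_58 ,  001002 001008 005003 003001 001001 001001
isolated_59 ,  001001 001001 005005 003003 001001 001001
isolated_60 ,  001001 002001 006001 001003 001001 001001
Pop
source_1 ,  001001 004001 001002 001001 001001 001001
source_2 ,  001005 001001 001001 001001 001001 001001
source_3 ,  001005 006001 005001 001001 001001 001001
source_4 ,  004002 007004 003005 001002 001001 001001
source_5 ,  004006 008006 001005 006001 001001 001001
source_6 ,  003001 001001 003002 001002 001001 001001
source_7 ,  001004 008007 006003 001001 001001 001001
source_8 ,  006005 008001 005005 001003 001001 001001
source_9 ,  001001 008001 005001 001001 001001 001001
source_10 ,  005001 003006 003002 001001 001001 001001
source_11 ,  001005 007003 003006 001002 001001 001001
source_12 ,  003005 001005 001005 002001 001001 001001
source_13 ,  005005 004001 001004 004001 001001 001001
source_14 ,  005001 004004 003001 003001 001001 001001
source_15 ,  001005 001003 002005 001004 001001 001001
source_16 ,  001003 001001 002002 004001 001001 001001
source_17 ,  005001 001007 005001 001001 001001 001001
source_18 ,  002004 003008 001001 001001 001001 001001
source_19 ,  003006 008004 001001 001001 001001 001001
source_20 ,  002004 008001 003002 001001 001001 001001
source_21 ,  005003 003004 005004 004001 001001 001001
source_22 ,  001002 006003 005004 001001 001001 001001
source_23 ,  005005 003004 006003 005001 001001 001001
source_24 ,  006001 004008 002001 003006 001001 001001
source_25 ,  003001 007001 001001 001001 001001 001001
source_26 ,  004005 003003 004004 001001 001001 001001
source_27 ,  004001 003001 006001 004002 001001 001001
source_28 ,  001003 002003 003006 004001 001001 001001
source_29 ,  004001 001001 003005 003001 001001 001001
source_30 ,  002005 007001 002001 001003 001001 001001
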