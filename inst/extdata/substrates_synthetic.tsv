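name	group	sequence	loop_start	loop_len	class
SYN01	ncRNA	GCUCACAUCCUAAGAGAUCUUAGGAUGUGAGC	15	4	G2_NGNN
SYN02	ncRNA	CGAGAAUAUUUGGUUAGGUAACCAAAGAUUCUCU	16	4	G2_NGNN
SYN03	ncRNA	GGGGCUAGUUAUUUAUAGUUAUAAAUAACUAGCACC	17	4	G2_NGNN
SYN04	PCG	CCCCUAGAUACUAACAGAUGUUAGUAUCUAGGGG	16	4	G2_NGNN
SYN05	PCG	GCCUAGAUCCUGAUAGGUAUCAGGAUCUAGGC	15	4	G2_NGNN
SYN06	ncRNA	CGCGCUUAUUCUCAUAGUCAUGAGAAUAAGCGCG	16	4	G2_NGNN
SYN07	ncRNA	CCUUCCAGAUACUGAUAGAUAUCAGUAUCUGGAAGG	17	4	G2_NGNN
SYN08	ncRNA	GUGAGCAGAUCCAGCGCGGUCGCUGGCUCUGCUCCC	17	4	G2_NGNN
SYN09	PCG	GCCUAGAUUUUGAUAGUUAUCAAAAUCUAGGC	15	4	G2_NGNN
SYN10	PCG	CGCUCUGCUAUGAUAGAUAUCAUAGCAGAGCG	15	4	G2_NGNN
SYN11	ncRNA	GAGAGCAGAUUCCGAUAGGUAUCGGAAUCUGCUUUC	17	4	G2_NGNN
SYN12	ncRNA	UGCCAAGAAUCUGAUAGUCAUCAGAUCCUUGGCC	16	4	G2_NGNN
SYN13	ncRNA	GCGCCUAGAAUAGGAUAGAUAUCCUAUUCUAGGAGC	17	4	G2_NGNN
SYN14	PCG	AGCUUACAUUCCGAUAGGUAUCGGACUGUAAGCU	16	4	G2_NGNN
SYN15	PCG	GCUUAGAUUCUAAUAGUUAUUAGAAUCUAAGC	15	4	G2_NGNN
SYN16	ncRNA	GCCUACAUUCCAAUCGAUAUUGGAACGUAGGC	15	4	G2_NGNN
SYN17	ncRNA	CGUUUAUAUUUUGAUAGGUAUCAAAAUAUAAACU	16	4	G2_NGNN
SYN18	ncRNA	GCAUAGAUUCGCGAAGUCCCGCGAAGCUAUGC	15	4	G2_NGNN
SYN19	PCG	UGCCUAUAUCCUGAGAGAUCUCAGGAUAUAGGCA	16	4	G2_NGNN
SYN20	PCG	CGACUAUGUCCUGAGAGGUCUCAGGACAUAGUCG	16	4	G2_NGNN
SYN21	ncRNA	GCUUCCAGAAUCGGCUAGUUAGCCGAUUCUGGAAAC	17	4	G2_NGNN
SYN22	ncRNA	CGCGUAGGUUCUGAGAGAUCUCAGAACCUACGCA	16	4	G2_NGNN
SYN23	ncRNA	UCGCCUAUAUUCUGAUAGGUAUCAGAACAUAGGUGA	17	4	G2_NGNN
SYN24	PCG	GCACCACGAUUCUGAUCGUCAUCAGAAUCGUGGUGC	17	4	G2_NGNN
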