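cdr3	gene	species	antigen.species
CASSLAPGATNEKLFF	TRB	HomoSapiens	CMV
CASSPKTGAVFF	TRB	HomoSapiens	CMV
CASSLVGGPSSEAFF	TRB	HomoSapiens	CMV
CASSFQGYTEAFF	TRB	HomoSapiens	CMV
CASSLEGQQPQHF	TRB	HomoSapiens	CMV
CASSIGVRETQYF	TRB	HomoSapiens	CMV
CASSPQRNTEAFF	TRB	HomoSapiens	CMV
CASSYVRTGELFF	TRB	HomoSapiens	CMV
CASSLTGGRNQPQHF	TRB	HomoSapiens	CMV
CASSQDRGHTGELFF	TRB	HomoSapiens	CMV
CASSEARGGVEKLFF	TRB	HomoSapiens	CMV
CASSLGHRDSSYEQYF	TRB	HomoSapiens	CMV
CASSPGDEQFF	TRB	HomoSapiens	CMV
CASRDWDYTDTQYF	TRB	HomoSapiens	CMV
CASSALGGAGTGELFF	TRB	HomoSapiens	CMV
CASSQSPGGTQYF	TRB	HomoSapiens	EBV
CASSLGQAYEQYF	TRB	HomoSapiens	EBV
CASSARSGELFF	TRB	HomoSapiens	EBV
CASSSDRVGQETQYF	TRB	HomoSapiens	EBV
CASSPGTGGNEQFF	TRB	HomoSapiens	EBV
CASSLLGGWSEAFF	TRB	HomoSapiens	EBV
CASSYSRGDEQYF	TRB	HomoSapiens	EBV
CASSGQGAYEQYF	TRB	HomoSapiens	EBV
CASSPTGGELFF	TRB	HomoSapiens	EBV
CASSFTGSSYEQYF	TRB	HomoSapiens	EBV
CASSQNRGQETQYF	TRB	HomoSapiens	EBV
CASSLSGSAYNEQFF	TRB	HomoSapiens	EBV
CASSLAPGATNEKLFF	TRB	HomoSapiens	CMV
CAVRDSNYQLIW	TRA	HomoSapiens	CMV
CASSDAGGRNTLYF	TRB	MusMusculus	CMV
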