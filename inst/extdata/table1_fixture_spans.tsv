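"participant_id"	"picture_id"	"start"	"end"	"head_lemma"	"is_pronoun"	"is_null_subject"	"anaphoric"	"generic"	"anomaly"	"expected_category"
"TBL1"	1	0	3	"adam"	FALSE	FALSE	NA	NA	0	"indefinite_dp"
"TBL1"	1	3	5	"adam"	FALSE	FALSE	NA	NA	0	"definite_dp"
"TBL1"	1	7	8	"adam"	FALSE	FALSE	NA	NA	0	"bare_anaphoric"
"TBL1"	1	11	12	"tarla"	FALSE	FALSE	NA	NA	0	"bare_specific"
"TBL1"	1	13	14	"ev"	FALSE	FALSE	NA	NA	0	"bare_indefinite"
"TBL1"	1	15	17	"hayat"	FALSE	FALSE	NA	TRUE	0	"bare_generic"
"TBL1"	1	18	19	"kız"	FALSE	FALSE	NA	NA	0	"bare_residual"
"TBL1"	1	22	22	""	FALSE	TRUE	NA	NA	0	"null_subject"
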