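sample	rank	name	start	end	ref_start	ref_end
normal	1	miR-24-A	44	63	44	65
normal	2	miR-143-U	61	82	61	81
normal	3	miR-424-A	11	33	11	32
normal	4	miR-145-A	16	36	16	38
normal	5	miR-515-U	51	74	51	72
normal	6	miR-103-U	48	70	NA	NA
normal	7	miR-515-U	51	73	51	72
normal	8	miR-24-A	44	65	NA	NA
normal	9	miR-199a-A	47	69	47	68
normal	10	miR-521-A	54	75	NA	NA
mild	1	miR-24-A	44	65	NA	NA
mild	2	miR-24-U	44	66	44	65
mild	3	miR-519d-A	54	76	54	75
mild	4	miR-517a-A	54	75	NA	NA
mild	5	miR-518e-A	54	75	54	74
mild	6	miR-24-A	44	63	44	65
mild	7	miR-24-U	44	65	NA	NA
mild	8	miR-517a-C	54	75	NA	NA
mild	9	miR-145-A	16	36	16	38
mild	10	miR-521-A	54	75	NA	NA
severe	1	miR-24-A	44	65	NA	NA
severe	2	miR-24-U	44	66	44	65
severe	3	miR-519d-A	54	76	54	75
severe	4	miR-24-A	44	66	44	65
severe	5	miR-517a-A	54	75	NA	NA
severe	6	miR-517a-C	54	75	NA	NA
severe	7	miR-518c-A	62	84	NA	NA
severe	8	miR-103-U	48	70	NA	NA
severe	9	miR-29a-A	42	64	42	63
severe	10	miR-519d-C	54	76	54	75
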