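sample	scheme	rank	mature_id
normal	most	1	miR-24
normal	most	2	miR-521
normal	most	3	miR-29b
normal	most	4	miR-103
normal	most	5	miR-515
normal	most	6	miR-424
normal	most	7	miR-143
normal	most	8	miR-145
normal	most	9	miR-23a
normal	most	10	miR-29c
normal	sum	1	miR-24
normal	sum	2	miR-515
normal	sum	3	miR-145
normal	sum	4	miR-143
normal	sum	5	miR-424
normal	sum	6	miR-521
normal	sum	7	miR-29b
normal	sum	8	miR-103
normal	sum	9	miR-23a
normal	sum	10	miR-29c
mild	most	1	miR-24
mild	most	2	miR-517a
mild	most	3	miR-519a
mild	most	4	miR-519d
mild	most	5	miR-517c
mild	most	6	miR-521
mild	most	7	miR-23a
mild	most	8	miR-103
mild	most	9	miR-520g
mild	most	10	miR-451
mild	sum	1	miR-24
mild	sum	2	miR-517a
mild	sum	3	miR-519d
mild	sum	4	miR-519a
mild	sum	5	miR-23a
mild	sum	6	miR-451
mild	sum	7	miR-520g
mild	sum	8	miR-517c
mild	sum	9	miR-521
mild	sum	10	miR-103
severe	most	1	miR-24
severe	most	2	miR-517a
severe	most	3	miR-519d
severe	most	4	miR-519a
severe	most	5	miR-103
severe	most	6	miR-29a
severe	most	7	miR-130a
severe	most	8	miR-517c
severe	most	9	miR-23a
severe	most	10	miR-29c
severe	sum	1	miR-24
severe	sum	2	miR-517a
severe	sum	3	miR-519d
severe	sum	4	miR-519a
severe	sum	5	miR-23a
severe	sum	6	miR-103
severe	sum	7	miR-29a
severe	sum	8	miR-517c
severe	sum	9	miR-130a
severe	sum	10	miR-29c
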