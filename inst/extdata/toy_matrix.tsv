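sample_id	role	marker_system	primer_combo	band_label	channel	presence
Korso	RECURRENT_PARENT	AFLP	E45-M57	150bp		1
G1_1	DONOR_PARENT	AFLP	E45-M57	150bp		1
B_carinata	REFERENCE	AFLP	E45-M57	150bp		1
IL1	IL	AFLP	E45-M57	150bp		1
IL11	IL	AFLP	E45-M57	150bp		1
Korso	RECURRENT_PARENT	AFLP	E45-M57	165bp		1
G1_1	DONOR_PARENT	AFLP	E45-M57	165bp		1
B_carinata	REFERENCE	AFLP	E45-M57	165bp		0
IL1	IL	AFLP	E45-M57	165bp		1
IL11	IL	AFLP	E45-M57	165bp		1
Korso	RECURRENT_PARENT	AFLP	E45-M57	214bp		1
G1_1	DONOR_PARENT	AFLP	E45-M57	214bp		0
B_carinata	REFERENCE	AFLP	E45-M57	214bp		0
IL1	IL	AFLP	E45-M57	214bp		0
IL11	IL	AFLP	E45-M57	214bp		1
Korso	RECURRENT_PARENT	AFLP	E45-M57	230bp		1
G1_1	DONOR_PARENT	AFLP	E45-M57	230bp		0
B_carinata	REFERENCE	AFLP	E45-M57	230bp		1
IL1	IL	AFLP	E45-M57	230bp		1
IL11	IL	AFLP	E45-M57	230bp		1
Korso	RECURRENT_PARENT	AFLP	E45-M57	300bp		0
G1_1	DONOR_PARENT	AFLP	E45-M57	300bp		0
B_carinata	REFERENCE	AFLP	E45-M57	300bp		1
IL1	IL	AFLP	E45-M57	300bp		0
IL11	IL	AFLP	E45-M57	300bp		0
Korso	RECURRENT_PARENT	AFLP	E45-M57	410bp		0
G1_1	DONOR_PARENT	AFLP	E45-M57	410bp		0
B_carinata	REFERENCE	AFLP	E45-M57	410bp		0
IL1	IL	AFLP	E45-M57	410bp		1
IL11	IL	AFLP	E45-M57	410bp		0
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	180bp	H	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	180bp	M	1
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	180bp	H	0
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	180bp	M	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	180bp	H	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	180bp	M	0
IL1	IL	MSAP	ETTC+HMTCC	180bp	H	1
IL1	IL	MSAP	ETTC+HMTCC	180bp	M	0
IL11	IL	MSAP	ETTC+HMTCC	180bp	H	1
IL11	IL	MSAP	ETTC+HMTCC	180bp	M	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	210bp	H	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	210bp	M	0
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	210bp	H	0
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	210bp	M	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	210bp	H	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	210bp	M	0
IL1	IL	MSAP	ETTC+HMTCC	210bp	H	1
IL1	IL	MSAP	ETTC+HMTCC	210bp	M	0
IL11	IL	MSAP	ETTC+HMTCC	210bp	H	1
IL11	IL	MSAP	ETTC+HMTCC	210bp	M	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	260bp	H	0
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	260bp	M	1
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	260bp	H	0
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	260bp	M	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	260bp	H	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	260bp	M	0
IL1	IL	MSAP	ETTC+HMTCC	260bp	H	0
IL1	IL	MSAP	ETTC+HMTCC	260bp	M	0
IL11	IL	MSAP	ETTC+HMTCC	260bp	H	0
IL11	IL	MSAP	ETTC+HMTCC	260bp	M	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	320bp	H	1
Korso	RECURRENT_PARENT	MSAP	ETTC+HMTCC	320bp	M	1
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	320bp	H	1
G1_1	DONOR_PARENT	MSAP	ETTC+HMTCC	320bp	M	1
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	320bp	H	0
B_carinata	REFERENCE	MSAP	ETTC+HMTCC	320bp	M	0
IL1	IL	MSAP	ETTC+HMTCC	320bp	H	1
IL1	IL	MSAP	ETTC+HMTCC	320bp	M	1
IL11	IL	MSAP	ETTC+HMTCC	320bp	H	1
IL11	IL	MSAP	ETTC+HMTCC	320bp	M	1
Korso	RECURRENT_PARENT	SSR	At3	At3g55005a		0
G1_1	DONOR_PARENT	SSR	At3	At3g55005a		1
B_carinata	REFERENCE	SSR	At3	At3g55005a		0
IL1	IL	SSR	At3	At3g55005a		0
IL11	IL	SSR	At3	At3g55005a		1
Korso	RECURRENT_PARENT	SSR	Na12	nia-m037a		0
G1_1	DONOR_PARENT	SSR	Na12	nia-m037a		1
B_carinata	REFERENCE	SSR	Na12	nia-m037a		0
IL1	IL	SSR	Na12	nia-m037a		0
IL11	IL	SSR	Na12	nia-m037a		1
Korso	RECURRENT_PARENT	SSR	Na14	cnu-m472a		1
G1_1	DONOR_PARENT	SSR	Na14	cnu-m472a		0
B_carinata	REFERENCE	SSR	Na14	cnu-m472a		0
IL1	IL	SSR	Na14	cnu-m472a		1
IL11	IL	SSR	Na14	cnu-m472a		1
Korso	RECURRENT_PARENT	SSR	Na15	cnu-m052a		0
G1_1	DONOR_PARENT	SSR	Na15	cnu-m052a		0
B_carinata	REFERENCE	SSR	Na15	cnu-m052a		1
IL1	IL	SSR	Na15	cnu-m052a		0
IL11	IL	SSR	Na15	cnu-m052a		1
Korso	RECURRENT_PARENT	SSR	Ol10	BrID10227		0
G1_1	DONOR_PARENT	SSR	Ol10	BrID10227		1
B_carinata	REFERENCE	SSR	Ol10	BrID10227		0
IL1	IL	SSR	Ol10	BrID10227		1
IL11	IL	SSR	Ol10	BrID10227		1
Korso	RECURRENT_PARENT	SSR	Ol11	BrID10205		1
G1_1	DONOR_PARENT	SSR	Ol11	BrID10205		0
B_carinata	REFERENCE	SSR	Ol11	BrID10205		0
IL1	IL	SSR	Ol11	BrID10205		1
IL11	IL	SSR	Ol11	BrID10205		0
Korso	RECURRENT_PARENT	SSR	Ol12	BrID10101		1
G1_1	DONOR_PARENT	SSR	Ol12	BrID10101		1
B_carinata	REFERENCE	SSR	Ol12	BrID10101		0
IL1	IL	SSR	Ol12	BrID10101		1
IL11	IL	SSR	Ol12	BrID10101		1
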