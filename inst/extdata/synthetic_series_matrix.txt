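!Series_title	"Synthetic miniature series for parser tests"
!Series_geo_accession	"GSE00000"
!Sample_geo_accession	"GSM1"	"GSM2"	"GSM3"	"GSM4"	"GSM5"
!Sample_title	"subj1 baseline"	"subj1 peak"	"subj2 baseline"	"subj2 peak"	"control"
!Sample_characteristics_ch1	"infection: none"	"infection: hrv"	"infection: none"	"infection: rsv"	"infection: none"
!Sample_characteristics_ch1	"timepoint: baseline"	"timepoint: peak"	"timepoint: baseline"	"timepoint: peak"	"timepoint: baseline"
!series_matrix_table_begin
"ID_REF"	"GSM1"	"GSM2"	"GSM3"	"GSM4"	"GSM5"
"probe_1"	7.25	8.5	7.1	8.9	7.3
"probe_2"	5.5	5.25	5.75	5.4	5.6
"probe_3"	10	11.5	9.75	12	10.25
"probe_4"	6.125	6	6.25	6.1	6.2
!series_matrix_table_end
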