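measure	patient_mean	patient_sd	control_mean	control_sd	n_patient	n_control
age	68.50	7.77	67.19	8.38	16	16
education	10.06	3.91	9.06	3.64	16	16
MMSE	25.94	1.65	28.56	0.63	16	16
CVLT_immediate	8.39	1.23	11.33	1.86	16	16
CVLT_short	9.13	1.23	13.00	1.86	16	16
CVLT_long	7.31	1.43	12.62	1.36	16	16
CDT	5.75	0.54	8.62	1.36	16	16
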