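# Radiobiology parameter presets: gEUD exponent a, midpoint dose (Gy), slope.
# Literature-derived defaults in the midpoint-logistic parameterization;
# negative a rows are tumor targets (td50_gy is then TCD50). Users should
# review and replace these with institution-fitted values before clinical use.
organ	a	td50_gy	gamma50
brain_necrosis	5	60	3
brainstem_necrosis	7	65	3
optic_chiasm_blindness	25	65	3
spinal_cord_myelitis	13	66.5	4
parotid_xerostomia	0.5	46	1.8
larynx_edema	8	70	4
lung_pneumonitis	1	24.5	2
heart_pericarditis	3	50	3
tumor_generic	-10	50	2
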