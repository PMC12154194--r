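sample_id	subject_id	tissue	condition
liver_M01	M01	liver	thermoneutral_30C
liver_M02	M02	liver	thermoneutral_30C
liver_M03	M03	liver	thermoneutral_30C
liver_M04	M04	liver	thermoneutral_30C
liver_M05	M05	liver	thermoneutral_30C
liver_M06	M06	liver	thermoneutral_30C
liver_M07	M07	liver	cold_5C
liver_M08	M08	liver	cold_5C
liver_M09	M09	liver	cold_5C
liver_M10	M10	liver	cold_5C
liver_M11	M11	liver	cold_5C
liver_M12	M12	liver	cold_5C
sWAT_M01	M01	sWAT	thermoneutral_30C
sWAT_M02	M02	sWAT	thermoneutral_30C
sWAT_M03	M03	sWAT	thermoneutral_30C
sWAT_M04	M04	sWAT	thermoneutral_30C
sWAT_M05	M05	sWAT	thermoneutral_30C
sWAT_M06	M06	sWAT	thermoneutral_30C
sWAT_M07	M07	sWAT	cold_5C
sWAT_M08	M08	sWAT	cold_5C
sWAT_M09	M09	sWAT	cold_5C
sWAT_M10	M10	sWAT	cold_5C
sWAT_M11	M11	sWAT	cold_5C
sWAT_M12	M12	sWAT	cold_5C
eWAT_M01	M01	eWAT	thermoneutral_30C
eWAT_M02	M02	eWAT	thermoneutral_30C
eWAT_M03	M03	eWAT	thermoneutral_30C
eWAT_M04	M04	eWAT	thermoneutral_30C
eWAT_M05	M05	eWAT	thermoneutral_30C
eWAT_M06	M06	eWAT	thermoneutral_30C
eWAT_M07	M07	eWAT	cold_5C
eWAT_M08	M08	eWAT	cold_5C
eWAT_M09	M09	eWAT	cold_5C
eWAT_M10	M10	eWAT	cold_5C
eWAT_M11	M11	eWAT	cold_5C
eWAT_M12	M12	eWAT	cold_5C
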