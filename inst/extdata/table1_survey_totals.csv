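season,survey_date,effort_km,photo_records,guanacos
non-breeding,2009-05-10,294,842,1618
non-breeding,2009-05-09,289.24,969,1572
breeding,2010-03-02,295,923,1406
breeding,2010-03-04,353,1049,1686
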