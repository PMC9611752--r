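{
  "_note": "Starting column mapping for a CPS ASEC person-file export that has already been converted to delimited text. Values must additionally be recoded to the canonical labels the pipeline filters expect (race: 'White'/'Black', sex: 'Male'/'Female', nativity: 'Native', employment: 'Full-time', health: integers 1-5); pass the recoded file to load_person_table() with this map.",
  "race": "PRDTRACE",
  "sex": "A_SEX",
  "age": "A_AGE",
  "nativity": "PRCITSHP",
  "employment": "WEWKRS",
  "income": "PTOTVAL",
  "health": "HEA"
}
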