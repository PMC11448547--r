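id,country,sex,birth_date,death_date,death_year_only
r1,AA,F,1889-03-01,2001-03-01,
r2,AA,F,1888-06-15,2000-06-15,
r3,AA,F,1889-12-01,2003-05-10,
r4,AA,F,1893-06-01,2004-06-01,
r5,AA,M,1895-02-01,2005-09-01,
r6,BB,F,1897-04-01,2008-04-01,
r7,BB,unknown,1899-10-01,2010-01-15,
r8,BB,F,1900-07-01,,2011
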