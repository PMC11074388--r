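plate_id,species,sex,pregnant,capture_date,latitude,longitude,n_subsamples,n_cycles,growth_rate
Bm01,blue,M,na,1948-01-04,-64.67,158.40,84,5,15.20
Bm02,blue,F,no,1948-02-12,-74.65,172.47,85,2,
Bm03,blue,F,yes,1948-02-07,-67.30,169.20,82,1,
Bm04,blue,M,na,1948-02-24,-74.40,174.58,80,2,
Bm05,blue,F,yes,1948-02-14,-75.25,173.08,90,6,13.50
Bp01,fin,M,na,1947-12-31,-63.68,160.27,74,1,
Bp02,fin,M,na,1948-01-15,-65.33,158.77,72,4,16.25
Bp03,fin,F,yes,1948-01-12,-65.25,155.67,82,5,14.80
Bp04,fin,F,yes,1948-01-29,-64.68,161.95,71,2,
Bp05,fin,F,no,1948-02-03,-66.53,164.73,82,4,18.50
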