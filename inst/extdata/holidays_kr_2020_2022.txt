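# Korean public holidays, 2020-05-27 .. 2022-11-21 (27 days).
# Eight recurring types: Independence Movement Day (Mar 1), Children's Day
# (May 5), Buddha's Birthday (lunar), Memorial Day (Jun 6), Constitution Day
# (Jul 17), National Liberation Day (Aug 15), Chuseok (lunar, 3 days),
# Hangeul Proclamation Day (Oct 9).
2020-06-06
2020-07-17
2020-08-15
2020-09-30
2020-10-01
2020-10-02
2020-10-09
2021-03-01
2021-05-05
2021-05-19
2021-06-06
2021-07-17
2021-08-15
2021-09-20
2021-09-21
2021-09-22
2021-10-09
2022-03-01
2022-05-05
2022-05-08
2022-06-06
2022-07-17
2022-08-15
2022-09-09
2022-09-10
2022-09-11
2022-10-09
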