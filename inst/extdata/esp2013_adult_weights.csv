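# 2013 European standard population, adult age groups (20+), weights per
# 100,000 total population; 5-year ESP2013 weights summed into the five
# adult analysis groups (source: Eurostat, Revision of the European Standard
# Population, 2013 edition).
age_group,weight_per_100k
20-44,32500
45-64,26500
65-74,10500
75-84,6500
85+,2500
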