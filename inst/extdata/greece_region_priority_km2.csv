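region,area_km2
Peloponnese,22.75
Central Greece,18.5
East Macedonia and Thrace,9.25
West Greece,7
North Aegean,5.25
Attica,4.75
South Aegean,2.75
Thessaly,2.25
Epirus,1.5
Crete,1.5
Ionian Islands,1.25
Central Macedonia,0.5
West Macedonia,0
Mount Athos,0
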