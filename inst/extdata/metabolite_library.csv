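# Reference metabolite peak library (synthetic peak tables), version 1.
# 20 metabolites routinely profiled by colloid-enhanced SERS of cell lysates.
# peaks column: semicolon-separated "shift:relative_amplitude:half_width"
# (cm^-1, unitless with max 1 per record, cm^-1).
# Peak positions at 510/542 (S-S), 624 (C-C twist), 650 (C-S), 728 (adenine
# ring), 753 (indole/purine breathing), 1077 (C-C), 1150, 1320 (purine ring),
# 1331 (CH deformation), 1441/1450 (CH2 deformation), 1560 (COO-) and
# 1571 (C-N/C-C stretching) follow standard band assignments; all remaining
# positions, and every relative amplitude and width, are synthetic values
# chosen to give each metabolite a distinct fingerprint.
name,abbreviation,formula,peaks
spermine,Spm,C10H26N4,1571:1.0:8;1441:0.3:9;1003:0.35:10
isoleucine,Ile,C6H13NO2,1331:1.0:8;1450:0.80:8;1571:0.45:8;869:0.30:9
taurine,Tau,C2H7NO3S,1077:1.0:8;650:0.70:8;1571:0.40:8
xanthine,Xan,C5H4N4O2,650:1.0:8;1320:0.50:8;1571:0.60:8
L-carnosine,Car,C9H14N4O3,1441:1.0:8;1571:0.50:8;978:0.40:9
L-glutamine,Gln,C5H10N2O3,1150:1.0:9;1560:0.70:8;1571:0.50:8
adenine,Ade,C5H5N5,728:1.0:8;1320:0.80:8;1571:0.60:8;624:0.35:8
pyridoxine,VB6,C8H11NO3,1232:1.0:10;1571:0.55:8;812:0.40:9
serotonin,5-HT,C10H12N2O,753:1.0:8;1571:0.50:8;1340:0.45:9
acetylcholine chloride,AChCl,C7H16ClNO2,1441:1.0:8;717:0.80:8;1571:0.35:8
hypoxanthine,Hyp,C5H4N4O,650:1.0:8;728:0.90:8;1571:0.50:8
cystine,Cys,C6H12N2O4S2,542:1.0:8;510:0.80:8;1571:0.40:8
glycine,Gly,C2H5NO2,1327:1.0:8;893:0.70:8
L-alanine,Ala,C3H7NO2,850:1.0:8;1450:0.60:8
L-phenylalanine,Phe,C9H11NO2,1003:1.0:7;624:0.60:8
glutathione,GSH,C10H17N3O6S,650:1.0:8;1450:0.50:8;1120:0.35:10
creatinine,Cre,C4H7N3O,680:1.0:8;1420:0.50:9
uric acid,UA,C5H4N4O3,640:1.0:8;1133:0.60:8;1593:0.50:8
D-glucose,Glc,C6H12O6,1360:1.0:10;1124:0.80:10;518:0.30:10
L-lactic acid,Lac,C3H6O3,830:1.0:8;1450:0.45:8
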