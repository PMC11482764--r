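delta_mass	interpretation	category	formula_change
15.994915	oxidation (hydroxylation / oxygen gain)	metabolism	O
-15.994915	deoxygenation (oxygen loss)	metabolism	-O
14.015650	methylation	metabolism	CH2
-14.015650	demethylation	metabolism	-CH2
28.031300	ethylation	metabolism	C2H4
-28.031300	deethylation	metabolism	-C2H4
176.032088	glucuronidation	metabolism	C6H8O6
79.956815	sulfation	metabolism	SO3
42.010565	acetylation	metabolism	C2H2O
88.052430	C4H8O2 gain (e.g. hydroxybutyrylation / ester)	metabolism	C4H8O2
2.015650	hydrogenation	metabolism	H2
-2.015650	dehydrogenation	metabolism	-H2
18.010565	hydration	metabolism	H2O
-18.010565	dehydration (water loss)	metabolism	-H2O
30.010565	hydroxymethylation	metabolism	CH2O
162.052823	glycosylation (hexose)	metabolism	C6H10O5
27.994915	formylation (CO gain)	metabolism	CO
43.989829	carboxylation	metabolism	CO2
-43.989829	decarboxylation	metabolism	-CO2
-17.026549	ammonia loss	metabolism	-NH3
26.015650	C2H2 gain	metabolism	C2H2
13.979265	ketone formation (O gain with H2 loss)	metabolism
17.026549	ammonium adduct	adduct	NH3
21.981944	sodium adduct (Na for H)	adduct
37.955882	potassium adduct (K for H)	adduct
1.003355	13C isotope (+1)	isotope
1.997050	+2 isotope spacing (Cl/Br/S)	isotope
2.006710	two 13C isotopes (+2)	isotope
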