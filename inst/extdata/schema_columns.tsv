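dialect	column	type	units	description
supplement	Species	string		species label; accepted: boar / wild boar / sus scrofa; black bear / asian black bear / ursus thibetanus
supplement	T	numeric	years	time of sample collection in years since the accident (365.25 days/year)
supplement	District	string		district of collection
supplement	Municipality	string		municipality of collection
supplement	LnCs_c	numeric	ln(Bq/kg)	ln total radiocesium (134Cs+137Cs) activity, decay-corrected to the collection date
supplement	BelowDetection	logical		optional; TRUE rows are excluded from the analysis set and counted
raw	Species	string		as above
raw	CollectionDate	date	ISO-8601	day of collection (YYYY-MM-DD or YYYY/MM/DD)
raw	MeasurementDate	date	ISO-8601	day the activity result was obtained; must be on or after CollectionDate
raw	District	string		district of collection
raw	Municipality	string		municipality of collection
raw	Cs134	numeric	Bq/kg	134Cs activity at the measurement date (optional when CsTotal given)
raw	Cs137	numeric	Bq/kg	137Cs activity at the measurement date (optional when CsTotal given)
raw	CsTotal	numeric	Bq/kg	total radiocesium activity at the measurement date (defaults to Cs134+Cs137)
raw	BelowDetection	logical		optional; TRUE rows are excluded from the analysis set and counted
chernobyl	Zone	string		Alienation / Permanent_control / Periodic_control
chernobyl	Time	numeric	years	years since the 1986 accident
chernobyl	N	integer	animals	number of animals summarised in the cell
chernobyl	LnMeanCs	numeric	ln(Bq/kg)	ln mean 137Cs level in muscle
chernobyl	LnMinCs	numeric	ln(Bq/kg)	ln minimum 137Cs level
chernobyl	LnMaxCs	numeric	ln(Bq/kg)	ln maximum 137Cs level
chernobyl	LnMeanCs_c	numeric	ln ratio	LnMeanCs minus ln decay-corrected land contamination of the zone
chernobyl	Weight	numeric	dimensionless	optional; n/(LnMaxCs-LnMinCs)^2 normalised to mean 1 (recomputed when absent)
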