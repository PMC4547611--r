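# Controlled-vocabulary homogenisation rules: native field names of each
# source format mapped onto PSI-MS terms, so the same concept carries the
# same accession regardless of origin. Unmapped keys pass through as
# userParams (never dropped).
# source_format	source_key	cv_label	accession	name
mgf	TITLE	MS	MS:1000796	spectrum title
mgf	PEPMASS	MS	MS:1000744	selected ion m/z
mgf	CHARGE	MS	MS:1000041	charge state
mgf	RTINSECONDS	MS	MS:1000894	retention time
mgf	SCANS	MS	MS:1000797	peak list scans
dta	MH	MS	MS:1000744	selected ion m/z
dta	CHARGE	MS	MS:1000041	charge state
pkl	PRECURSOR_MZ	MS	MS:1000744	selected ion m/z
pkl	PRECURSOR_INTENSITY	MS	MS:1000042	peak intensity
pkl	CHARGE	MS	MS:1000041	charge state
ms2	S	MS	MS:1000744	selected ion m/z
ms2	Z	MS	MS:1000041	charge state
ms2	RetTime	MS	MS:1000894	retention time
apl	header	MS	MS:1000796	spectrum title
apl	mz	MS	MS:1000744	selected ion m/z
apl	charge	MS	MS:1000041	charge state
mzxml	precursorMz	MS	MS:1000744	selected ion m/z
mzxml	precursorCharge	MS	MS:1000041	charge state
mzxml	retentionTime	MS	MS:1000894	retention time
mzdata	MassToChargeRatio	MS	MS:1000744	selected ion m/z
mzdata	ChargeState	MS	MS:1000041	charge state
pridexml	MassToChargeRatio	MS	MS:1000744	selected ion m/z
pridexml	ChargeState	MS	MS:1000041	charge state
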