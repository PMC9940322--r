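condition,system,pattern,description
NICU,CPT,99295,Initial inpatient neonatal critical care (deleted 2009-01-01)
NICU,CPT,99296,Subsequent inpatient neonatal critical care (deleted 2009-01-01)
NICU,CPT,99297,Subsequent inpatient neonatal critical care (deleted 2009-01-01)
NICU,CPT,99298,Subsequent intensive care (deleted 2009-01-01)
NICU,CPT,99299,Subsequent intensive care (deleted 2009-01-01)
NICU,CPT,99300,Subsequent intensive care (deleted 2009-01-01)
NICU,CPT,99468,Initial inpatient neonatal critical care per day (<=28 days of age)
NICU,CPT,99469,Subsequent inpatient neonatal critical care per day (<=28 days of age)
NICU,CPT,99477,Initial hospital intensive care per day (<=28 days of age)
NICU,CPT,99478,Subsequent intensive care per day (very low birth weight <1500 g)
NICU,CPT,99479,Subsequent intensive care per day (low birth weight 1500-2500 g)
NICU,CPT,99480,Subsequent intensive care per day (body weight 2501-5000 g)
RDS,ICD9_DX,769.xx,Respiratory distress syndrome in newborn
SEIZURE,ICD9_DX,779.0x,Convulsions in newborn
AV,ICD9_PC,96.7,Other continuous invasive mechanical ventilation
AV,ICD9_PC,96.70,Continuous invasive mechanical ventilation of unspecified duration
AV,ICD9_PC,96.71,Continuous invasive mechanical ventilation <96 consecutive hours
AV,ICD9_PC,96.72,Continuous invasive mechanical ventilation >=96 consecutive hours
AV,ICD9_PC,93.90,Non-invasive mechanical ventilation
BIRTH_INJURY,ICD9_DX,767.xx,Birth trauma
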