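internal_name,file,external_column,notes
individual_id,behavior.csv,<fill in>,focal female identifier
day,behavior.csv,<fill in>,recording day (1-28)
activity_cm_s,behavior.csv,<fill in>,daily activity in cm per second
feeding_min,behavior.csv,<fill in>,daily time in feeding zone in minutes
individual_id,sizes.csv,<fill in>,focal female identifier
age_days,sizes.csv,<fill in>,age at measurement in days
length_cm,sizes.csv,<fill in>,standard length in cm (convert if deposited in mm)
individual_id,broods.csv,<fill in>,focal female identifier
mother_id,broods.csv,<fill in>,mother identity (descent)
brood_id,broods.csv,<fill in>,unique brood identifier
age_at_parturition_days,broods.csv,<fill in>,female age at parturition in days
brood_size,broods.csv,<fill in>,number of offspring in the brood
individual_id,offspring.csv,<fill in>,focal female identifier
brood_id,offspring.csv,<fill in>,brood identifier
length_cm,offspring.csv,<fill in>,offspring standard length in cm
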