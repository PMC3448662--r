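# Shared constants (this file must sort first in R/).

# indication strata of the day-care population
INDICATIONS <- c("chronic_liver_disease", "inflammatory_bowel_disease",
                 "angiodysplasia", "other")

# the six unit costs varied in sensitivity and Monte Carlo analyses
VARIED_PARAMETERS <- c("drug_price_is", "drug_price_fcm", "staff_rate",
                       "indirect_rate", "device_cost", "nonhospital_cost")
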