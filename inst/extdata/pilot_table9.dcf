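config: pilot_table9
optout_asc: yes
optout_prior: -0.2

attribute: schedule
label: Payment schedule
codes: 1 3 6 12
levels: 1 month; 3 months; 6 months; 12 months
coding: linear
sign: negative
prior: -0.045
cost: no

attribute: timeliness
label: Timeliness of payments
codes: 0 1
levels: Delayed; Timely
coding: linear
sign: positive
prior: 0.5
cost: no

attribute: rate
label: Capitation rate per individual per year
codes: 1200 2400 3600 4800
levels: 1200 shillings; 2400 shillings; 3600 shillings; 4800 shillings
coding: linear
sign: positive
prior: 0.00014
cost: yes

attribute: services
label: Services to be paid by the capitation rate
codes: 0 1 2 3
levels: Consultation only; Consultation and drugs; Consultation and lab tests; Consultation, lab tests and drugs
coding: linear
sign: negative
prior: -0.17
cost: no

attribute: performance
label: Performance requirements
codes: 0 1
levels: Base rate only; Base rate plus performance bonus
coding: linear
sign: negative
prior: -0.5
cost: no
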