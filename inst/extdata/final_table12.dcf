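config: final_table12
optout_asc: yes
optout_prior: -0.2

attribute: schedule
label: Payment schedule
codes: 1 3 6 12
levels: 1 month (every month); 3 months (every quarter); 6 months (twice a year); 12 months (once a year)
coding: linear
sign: negative
prior: -0.045
cost: no

attribute: timeliness
label: Timeliness of payments
codes: 0 1 2
levels: Delayed by more than 3 months; Delayed by less than 3 months; Timely
coding: linear
sign: positive
prior: 0.25
cost: no

attribute: rate
label: Capitation rate per individual per year
codes: 800 1600 2400 3200
levels: 800 shillings; 1600 shillings; 2400 shillings; 3200 shillings
coding: linear
sign: positive
prior: 0.0002
cost: yes

attribute: services
label: Services to be paid by the capitation rate
codes: 0 1 2 3
levels: Consultation only; Consultation and laboratory tests; Consultation and drugs; Consultation, laboratory tests, drugs and imaging
coding: linear
sign: negative
prior: -0.17
cost: no
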