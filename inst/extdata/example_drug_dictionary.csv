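raw,generic
cytarabine inj.,cytarabine
ara-c,cytarabine
l-asparaginase,asparaginase
peg-asparaginase,pegaspargase
mtx,methotrexate
vcr,vincristine
cddp,cisplatin
ctx,cyclophosphamide
vp-16,etoposide
adriamycin,doxorubicin
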