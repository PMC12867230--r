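quantity,count,total,printed_pct,printed_digits
tp_share_study,1968,27793,7.08,2
tp_share_subset,1968,23409,8.41,2
donors_one_kidney,5225,16509,31.6,1
donors_two_kidneys,11284,16509,68.4,1
btd_candidates,21441,144206,14.9,1
txps_with_tp,138,231,59.74,2
non_btd_transplanted,23929,122765,19.5,1
btd_transplanted,3864,21441,18,0
btd_better_kidney,2443,3864,63.3,1
btd_same_kidney,17,3864,0.4,1
btd_worse_kidney,1404,3864,36.3,1
btd_dominating_offer,3845,3864,99.5,1
btd_dominating_offer_excl801,3836,3864,99.3,1
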