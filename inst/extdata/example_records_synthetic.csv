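trip_id,haul_id,haul_datetime,haul_catch_kg,length_cm,n_measured,raising_factor
T01,T01-H01,2018-07-15T19:35:11,4716.33310255129,100,1,237.629171634204
T01,T01-H01,2018-07-15T19:35:11,4716.33310255129,97,1,237.629171634204
T01,T01-H01,2018-07-15T19:35:11,4716.33310255129,32,1,237.629171634204
T01,T01-H01,2018-07-15T19:35:11,4716.33310255129,34,1,237.629171634204
T01,T01-H02,2018-07-15T01:22:58,2176.45811499096,74,1,143.673593915157
T01,T01-H02,2018-07-15T01:22:58,2176.45811499096,96,1,143.673593915157
T01,T01-H02,2018-07-15T01:22:58,2176.45811499096,31,1,143.673593915157
T01,T01-H02,2018-07-15T01:22:58,2176.45811499096,58,1,143.673593915157
T02,T02-H01,2018-07-15T19:16:04,4731.08081496321,69,1,430.486084732992
T02,T02-H01,2018-07-15T19:16:04,4731.08081496321,58,1,430.486084732992
T02,T02-H01,2018-07-15T19:16:04,4731.08081496321,67,1,430.486084732992
T02,T02-H01,2018-07-15T19:16:04,4731.08081496321,65,1,430.486084732992
T02,T02-H02,2018-07-15T02:30:19,3473.60649483744,78,1,219.648048732577
T02,T02-H02,2018-07-15T02:30:19,3473.60649483744,47,1,219.648048732577
T02,T02-H02,2018-07-15T02:30:19,3473.60649483744,99,1,219.648048732577
T02,T02-H02,2018-07-15T02:30:19,3473.60649483744,32,1,219.648048732577
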