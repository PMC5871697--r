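H     0
S    4   1.00
     50.9991780              0.0096605
      7.4832181              0.0737289
      1.7774676              0.2958581
      0.5193295              0.7159053
S    1   1.00
      0.1541100              1.0000000
****
He     0
S    5   1.00
    221.3880300              0.0027491
     33.2619660              0.0208658
      7.5616549              0.0970588
      2.0855990              0.2807289
      0.6143392              0.4742218
S    1   1.00
      0.1829212              1.0000000
****
C     0
S    6   1.00
   2808.0645000              0.0020178
    421.1382800              0.0154332
     95.5866160              0.0755815
     26.7390040              0.2478282
      8.4328268              0.4793725
      2.7605821              0.3338344
S    2   1.00
      5.4470045             -0.0778408
      0.4792422              0.5689560
S    1   1.00
      0.1461565              1.0000000
P    4   1.00
     18.1308520              0.0158547
      4.0998832              0.0956828
      1.1858370              0.3049119
      0.3685974              0.4935016
P    1   1.00
      0.1097200              1.0000000
D    1   1.00
      0.6000000              1.0000000
****
N     0
S    6   1.00
   3845.4149000              0.0020186
    577.5332300              0.0154078
    131.3198300              0.0753714
     36.8237810              0.2482122
     11.6701150              0.4798274
      3.8542604              0.3318012
S    2   1.00
      7.8295611             -0.0776669
      0.6877351              0.5654598
S    1   1.00
      0.2040388              1.0000000
P    4   1.00
     26.8098410              0.0154663
      6.0681540              0.0964397
      1.7676256              0.3083610
      0.5466727              0.4911597
P    1   1.00
      0.1587289              1.0000000
D    1   1.00
      0.7000000              1.0000000
****
O     0
S    6   1.00
   5222.9022000             -0.0019364
    782.5399400             -0.0148507
    177.2674300             -0.0733187
     49.5166880             -0.2451162
     15.6664400             -0.4802847
      5.1793599             -0.3359427
S    2   1.00
     10.6014410              0.0788058
      0.9423170             -0.5676952
S    1   1.00
      0.2774746              1.0000000
P    4   1.00
     33.4241260              0.0175603
      7.6221714              0.1076300
      2.2382093              0.3235256
      0.6867300              0.4832229
P    1   1.00
      0.1938135              1.0000000
D    1   1.00
      0.8000000              1.0000000
****
S     0
S    6   1.00
  23050.0670000             -0.0017567
   3451.8663000             -0.0134894
    781.2786700             -0.0674325
    218.4765300             -0.2318604
     69.8326320             -0.4749416
     23.4947980             -0.3564992
S    3   1.00
     46.4823770             -0.0940422
      4.8807488              0.5828881
      1.8014758              0.4923262
S    2   1.00
      2.9778039              0.1731553
      0.3942510             -0.6854363
S    1   1.00
      0.1417028              1.0000000
P    5   1.00
    231.3312600              0.0112789
     54.1461640              0.0794257
     16.7576180              0.2808799
      5.7193197              0.5020190
      1.9560351              0.3344146
P    2   1.00
      0.8955912              0.2646811
      0.3094227              0.5496127
P    1   1.00
      0.1021157              1.0000000
D    1   1.00
      0.6500000              1.0000000
****
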