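H     0
S    3   1.00
      0.1873113696D+02       0.3349460434D-01
      0.2825394365D+01       0.2347269535D+00
      0.6401216923D+00       0.8137573261D+00
S    1   1.00
      0.1612777588D+00       1.0000000
****
He     0
S    3   1.00
      0.3842163400D+02       0.4013973935D-01
      0.5778030000D+01       0.2612460970D+00
      0.1241774000D+01       0.7931846246D+00
S    1   1.00
      0.2979640000D+00       1.0000000
****
C     0
S    6   1.00
      0.3047524880D+04       0.1834737132D-02
      0.4573695180D+03       0.1403732281D-01
      0.1039486850D+03       0.6884262226D-01
      0.2921015530D+02       0.2321844432D+00
      0.9286662960D+01       0.4679413484D+00
      0.3163926960D+01       0.3623119853D+00
SP   3   1.00
      0.7868272350D+01      -0.1193324198D+00       0.6899906659D-01
      0.1881288540D+01      -0.1608541517D+00       0.3164239610D+00
      0.5442492580D+00       0.1143456438D+01       0.7443082909D+00
SP   1   1.00
      0.1687144782D+00       0.1000000000D+01       0.1000000000D+01
****
N     0
S    6   1.00
      0.4173511460D+04       0.1834772160D-02
      0.6274579110D+03       0.1399462700D-01
      0.1429020930D+03       0.6858655181D-01
      0.4023432930D+02       0.2322408730D+00
      0.1282021290D+02       0.4690699481D+00
      0.4390437010D+01       0.3604551991D+00
SP   3   1.00
      0.1162636186D+02      -0.1149611817D+00       0.6757974388D-01
      0.2716279807D+01      -0.1691174786D+00       0.3239072959D+00
      0.7722183966D+00       0.1145851947D+01       0.7408951398D+00
SP   1   1.00
      0.2120314975D+00       0.1000000000D+01       0.1000000000D+01
****
O     0
S    6   1.00
      0.5484671660D+04       0.1831074430D-02
      0.8252349460D+03       0.1395017220D-01
      0.1880469580D+03       0.6844507810D-01
      0.5296450000D+02       0.2327143360D+00
      0.1689757040D+02       0.4701928980D+00
      0.5799635340D+01       0.3585208530D+00
SP   3   1.00
      0.1553961625D+02      -0.1107775495D+00       0.7087426823D-01
      0.3599933586D+01      -0.1480262627D+00       0.3397528391D+00
      0.1013761750D+01       0.1130767015D+01       0.7271585773D+00
SP   1   1.00
      0.2700058226D+00       0.1000000000D+01       0.1000000000D+01
****
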