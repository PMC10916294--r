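# Octahedral-orbit parameters for the Lebedev-Laikov angular rules shipped
# with the package. Orbit codes follow the standard generator:
#   1: 6 points (+-1,0,0);  2: 12 points (0,+-q,+-q), q=1/sqrt(2);
#   3: 8 points (+-q,+-q,+-q), q=1/sqrt(3);  4: 24 points (a,a,b), b=sqrt(1-2a^2);
#   5: 24 points (a,b,0), b=sqrt(1-a^2);  6: 48 points (a,b,c), c=sqrt(1-a^2-b^2).
# Weights are normalised to sum 1 over the sphere (multiplied by 4*pi on expansion).
# Verified against exact integration of all real spherical harmonics up to the
# rule's design degree (residuals at machine precision).
.lebedev_orbit_tables <- list(
  "6" = list(degree = 3L, orbits = list(
    list(code = 1L, v = 0.1666666666666667)
  )),
  "26" = list(degree = 7L, orbits = list(
    list(code = 1L, v = 0.04761904761904762),
    list(code = 2L, v = 0.0380952380952381),
    list(code = 3L, v = 0.03214285714285714)
  )),
  "110" = list(degree = 17L, orbits = list(
    list(code = 1L, v = 0.003828270494937162),
    list(code = 3L, v = 0.009793737512487513),
    list(code = 4L, v = 0.008211737283191111, a = 0.1851156353447362),
    list(code = 4L, v = 0.009942814891178103, a = 0.6904210483822922),
    list(code = 4L, v = 0.009595471336070962, a = 0.3956894730559419),
    list(code = 5L, v = 0.009694996361663029, a = 0.4783690288121502)
  )),
  "302" = list(degree = 29L, orbits = list(
    list(code = 1L, v = 0.0008545911725128148),
    list(code = 3L, v = 0.003599119285025571),
    list(code = 4L, v = 0.003449788424305883, a = 0.3515640345570105),
    list(code = 4L, v = 0.003604822601419882, a = 0.6566329410219612),
    list(code = 4L, v = 0.003576729661743367, a = 0.4729054132581005),
    list(code = 4L, v = 0.002352101413689164, a = 0.09618308522614784),
    list(code = 4L, v = 0.003108953122413675, a = 0.2219645236294178),
    list(code = 4L, v = 0.003650045807677255, a = 0.7011766416089545),
    list(code = 5L, v = 0.002982344963171804, a = 0.2644152887060663),
    list(code = 5L, v = 0.00360082093221646, a = 0.5718955891878961),
    list(code = 6L, v = 0.003571540554273387, a = 0.2510034751770465, b = 0.8000727494073951),
    list(code = 6L, v = 0.00339231220500617, a = 0.1233548532583327, b = 0.4127724083168531)
  )),
  "590" = list(degree = 41L, orbits = list(
    list(code = 1L, v = 0.0003095121295306187),
    list(code = 3L, v = 0.001852379698597489),
    list(code = 4L, v = 0.001871790639277744, a = 0.7040954938227469),
    list(code = 4L, v = 0.001858812585438317, a = 0.6807744066455244),
    list(code = 4L, v = 0.001852028828296213, a = 0.6372546939258752),
    list(code = 4L, v = 0.001846715956151242, a = 0.5044419707800358),
    list(code = 4L, v = 0.001818471778162769, a = 0.4215761784010967),
    list(code = 4L, v = 0.001749564657281154, a = 0.3317920736472123),
    list(code = 4L, v = 0.001617210647254411, a = 0.2384736701421887),
    list(code = 4L, v = 0.001384737234851692, a = 0.1459036449157763),
    list(code = 4L, v = 0.000976433116505105, a = 0.06095034115507196),
    list(code = 5L, v = 0.001857161196774078, a = 0.6116843442009876),
    list(code = 5L, v = 0.001705153996395864, a = 0.3964755348199858),
    list(code = 5L, v = 0.001300321685886048, a = 0.1724782009907724),
    list(code = 6L, v = 0.001842866472905286, a = 0.561026380862206, b = 0.3518280927733519),
    list(code = 6L, v = 0.001802658934377451, a = 0.474239284255198, b = 0.263471665593795),
    list(code = 6L, v = 0.00184983056044366, a = 0.598412649788538, b = 0.1816640840360209),
    list(code = 6L, v = 0.001713904507106709, a = 0.3791035407695563, b = 0.1720795225656878),
    list(code = 6L, v = 0.001555213603396808, a = 0.2778673190586244, b = 0.08213021581932511),
    list(code = 6L, v = 0.001802239128008525, a = 0.5033564271075117, b = 0.08999205842074876)
  ))
)
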