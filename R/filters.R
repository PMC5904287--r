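# Two-channel filter banks for the wavelet bases used in the oscillation
# extraction model.  Coefficients are the standard published filters:
# Daubechies (dbN), symlets (symN), coiflets (coifN), Cohen-Daubechies-
# Feauveau biorthogonal spline pairs (biorX.Y) and their duals (rbioX.Y),
# and the discrete Meyer (dmey) FIR approximation.  Each entry holds the
# analysis pair (dec_lo, dec_hi) and the synthesis pair (rec_lo, rec_hi);
# biorthogonal pairs are zero-padded to a common even length.
.wp_filter_bank <- list(
  "sym4" = list(
    dec_lo = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614,
      0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
    dec_hi = c(-0.032223100604042702, -0.012603967262037833, 0.099219543576847216, 0.29785779560527736,
      -0.80373875180591614, 0.49761866763201545, 0.02963552764599851, -0.075765714789273325),
    rec_lo = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736,
      0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
    rec_hi = c(-0.075765714789273325, 0.02963552764599851, 0.49761866763201545, -0.80373875180591614,
      0.29785779560527736, 0.099219543576847216, -0.012603967262037833, -0.032223100604042702)),
  "sym5" = list(
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936,
      0.72340769040242059, 0.63397896345821192, 0.016602105764522319, -0.17532808990845047,
      -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.016602105764522319,
      -0.63397896345821192, 0.72340769040242059, -0.1993975339773936, -0.039134249302383094,
      -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.016602105764522319,
      0.63397896345821192, 0.72340769040242059, 0.1993975339773936, -0.039134249302383094,
      0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936,
      0.72340769040242059, -0.63397896345821192, 0.016602105764522319, 0.17532808990845047,
      -0.021101834024758855, -0.019538882735286728)),
  "sym8" = list(
    dec_lo = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981, 0.0076074873249176054,
      -0.14329423835080971, -0.061273359067658524, 0.48135965125837221, 0.77718575170052351,
      0.3644418948353314, -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
      0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668, 0.0018899503327594609),
    dec_hi = c(-0.0018899503327594609, -0.0003029205147213668, 0.014952258337048231, 0.0038087520138906151,
      -0.049137179673607506, -0.027219029917056003, 0.051945838107709037, 0.3644418948353314,
      -0.77718575170052351, 0.48135965125837221, 0.061273359067658524, -0.14329423835080971,
      -0.0076074873249176054, 0.031695087811492981, 0.00054213233179114812, -0.0033824159510061256),
    rec_lo = c(0.0018899503327594609, -0.0003029205147213668, -0.014952258337048231, 0.0038087520138906151,
      0.049137179673607506, -0.027219029917056003, -0.051945838107709037, 0.3644418948353314,
      0.77718575170052351, 0.48135965125837221, -0.061273359067658524, -0.14329423835080971,
      0.0076074873249176054, 0.031695087811492981, -0.00054213233179114812, -0.0033824159510061256),
    rec_hi = c(-0.0033824159510061256, 0.00054213233179114812, 0.031695087811492981, -0.0076074873249176054,
      -0.14329423835080971, 0.061273359067658524, 0.48135965125837221, -0.77718575170052351,
      0.3644418948353314, 0.051945838107709037, -0.027219029917056003, -0.049137179673607506,
      0.0038087520138906151, 0.014952258337048231, -0.0003029205147213668, -0.0018899503327594609)),
  "bior3.7" = list(
    dec_lo = c(0.0030210861012608843, -0.0090632583037826529, -0.016831765421310641, 0.074663985074019001,
      0.031332978707362888, -0.301159125922835, -0.026499240945345469, 0.95164212189717856,
      0.95164212189717856, -0.026499240945345469, -0.301159125922835, 0.031332978707362888,
      0.074663985074019001, -0.016831765421310641, -0.0090632583037826529, 0.0030210861012608843),
    dec_hi = c(-0, 0, -0, 0,
      -0, 0, -0.17677669529663689, 0.5303300858899106,
      -0.5303300858899106, 0.17677669529663689, -0, 0,
      -0, 0, -0, 0),
    rec_lo = c(0, 0, 0, 0,
      0, 0, 0.17677669529663689, 0.5303300858899106,
      0.5303300858899106, 0.17677669529663689, 0, 0,
      0, 0, 0, 0),
    rec_hi = c(0.0030210861012608843, 0.0090632583037826529, -0.016831765421310641, -0.074663985074019001,
      0.031332978707362888, 0.301159125922835, -0.026499240945345469, -0.95164212189717856,
      0.95164212189717856, 0.026499240945345469, -0.301159125922835, -0.031332978707362888,
      0.074663985074019001, 0.016831765421310641, -0.0090632583037826529, -0.0030210861012608843)),
  "bior1.5" = list(
    dec_lo = c(0.016572815184059706, -0.016572815184059706, -0.12153397801643785, 0.12153397801643785,
      0.70710678118654757, 0.70710678118654757, 0.12153397801643785, -0.12153397801643785,
      -0.016572815184059706, 0.016572815184059706),
    dec_hi = c(-0, 0, -0, 0,
      -0.70710678118654757, 0.70710678118654757, -0, 0,
      -0, 0),
    rec_lo = c(0, 0, 0, 0,
      0.70710678118654757, 0.70710678118654757, 0, 0,
      0, 0),
    rec_hi = c(0.016572815184059706, 0.016572815184059706, -0.12153397801643785, -0.12153397801643785,
      0.70710678118654757, -0.70710678118654757, 0.12153397801643785, 0.12153397801643785,
      -0.016572815184059706, -0.016572815184059706)),
  "db4" = list(
    dec_lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309,
      -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
    dec_hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892, -0.027983769416859854,
      0.18703481171909309, 0.030841381835560764, -0.032883011666885197, -0.010597401785069032),
    rec_lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854,
      -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309,
      -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651)),
  "db8" = list(
    dec_lo = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705, -0.0048703529934515741,
      0.0087460940474057766, 0.013981027917398282, -0.044088253930794755, -0.017369301001807547,
      0.12874742662047847, 0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
      0.58535468365420673, 0.67563073629728976, 0.31287159091429995, 0.054415842243104008),
    dec_hi = c(-0.054415842243104008, 0.31287159091429995, -0.67563073629728976, 0.58535468365420673,
      0.015829105256349306, -0.28401554296154691, -0.00047248457391328279, 0.12874742662047847,
      0.017369301001807547, -0.044088253930794755, -0.013981027917398282, 0.0087460940474057766,
      0.0048703529934515741, -0.00039174037337694705, -0.00067544940645056933, -0.00011747678412476953),
    rec_lo = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976, 0.58535468365420673,
      -0.015829105256349306, -0.28401554296154691, 0.00047248457391328279, 0.12874742662047847,
      -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
      -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933, -0.00011747678412476953),
    rec_hi = c(-0.00011747678412476953, -0.00067544940645056933, -0.00039174037337694705, 0.0048703529934515741,
      0.0087460940474057766, -0.013981027917398282, -0.044088253930794755, 0.017369301001807547,
      0.12874742662047847, -0.00047248457391328279, -0.28401554296154691, 0.015829105256349306,
      0.58535468365420673, -0.67563073629728976, 0.31287159091429995, -0.054415842243104008)),
  "rbio3.7" = list(
    dec_lo = c(0, 0, 0, 0,
      0, 0, 0.17677669529663689, 0.5303300858899106,
      0.5303300858899106, 0.17677669529663689, 0, 0,
      0, 0, 0, 0),
    dec_hi = c(-0.0030210861012608843, -0.0090632583037826529, 0.016831765421310641, 0.074663985074019001,
      -0.031332978707362888, -0.301159125922835, 0.026499240945345469, 0.95164212189717856,
      -0.95164212189717856, -0.026499240945345469, 0.301159125922835, 0.031332978707362888,
      -0.074663985074019001, -0.016831765421310641, 0.0090632583037826529, 0.0030210861012608843),
    rec_lo = c(0.0030210861012608843, -0.0090632583037826529, -0.016831765421310641, 0.074663985074019001,
      0.031332978707362888, -0.301159125922835, -0.026499240945345469, 0.95164212189717856,
      0.95164212189717856, -0.026499240945345469, -0.301159125922835, 0.031332978707362888,
      0.074663985074019001, -0.016831765421310641, -0.0090632583037826529, 0.0030210861012608843),
    rec_hi = c(0, -0, 0, -0,
      0, -0, 0.17677669529663689, -0.5303300858899106,
      0.5303300858899106, -0.17677669529663689, 0, -0,
      0, -0, 0, -0)),
  "rbio1.5" = list(
    dec_lo = c(0, 0, 0, 0,
      0.70710678118654757, 0.70710678118654757, 0, 0,
      0, 0),
    dec_hi = c(-0.016572815184059706, -0.016572815184059706, 0.12153397801643785, 0.12153397801643785,
      -0.70710678118654757, 0.70710678118654757, -0.12153397801643785, -0.12153397801643785,
      0.016572815184059706, 0.016572815184059706),
    rec_lo = c(0.016572815184059706, -0.016572815184059706, -0.12153397801643785, 0.12153397801643785,
      0.70710678118654757, 0.70710678118654757, 0.12153397801643785, -0.12153397801643785,
      -0.016572815184059706, 0.016572815184059706),
    rec_hi = c(0, -0, 0, -0,
      0.70710678118654757, -0.70710678118654757, 0, -0,
      0, -0)),
  "dmey" = list(
    dec_lo = c(0, -1.0099999569414229e-12, 8.519459636796214e-09, -1.111944952595278e-08,
      -1.0798819539621958e-08, 6.0669757413511352e-08, -1.0866516536735883e-07, 8.2006806503864813e-08,
      1.1783004497663934e-07, -5.5063405652522782e-07, 1.1307947017916706e-06, -1.4895492164971559e-06,
      7.367572885903746e-07, 3.2054419133447798e-06, -1.6312699734552807e-05, 6.5543059305751491e-05,
      -0.00060115023435160925, -0.002704672124643725, 0.0022025341009110021, 0.006045814097323304,
      -0.0063877183184971563, -0.011061496392513451, 0.015270015130934803, 0.017423434103729693,
      -0.032130793990211758, -0.024348745906078023, 0.063739024322801596, 0.030655091960824263,
      -0.13284520043622938, -0.035087555656258346, 0.44459300275757724, 0.74458559231880628,
      0.44459300275757724, -0.035087555656258346, -0.13284520043622938, 0.030655091960824263,
      0.063739024322801596, -0.024348745906078023, -0.032130793990211758, 0.017423434103729693,
      0.015270015130934803, -0.011061496392513451, -0.0063877183184971563, 0.006045814097323304,
      0.0022025341009110021, -0.002704672124643725, -0.00060115023435160925, 6.5543059305751491e-05,
      -1.6312699734552807e-05, 3.2054419133447798e-06, 7.367572885903746e-07, -1.4895492164971559e-06,
      1.1307947017916706e-06, -5.5063405652522782e-07, 1.1783004497663934e-07, 8.2006806503864813e-08,
      -1.0866516536735883e-07, 6.0669757413511352e-08, -1.0798819539621958e-08, -1.111944952595278e-08,
      8.519459636796214e-09, -1.0099999569414229e-12),
    dec_hi = c(1.0099999569414229e-12, 8.519459636796214e-09, 1.111944952595278e-08, -1.0798819539621958e-08,
      -6.0669757413511352e-08, -1.0866516536735883e-07, -8.2006806503864813e-08, 1.1783004497663934e-07,
      5.5063405652522782e-07, 1.1307947017916706e-06, 1.4895492164971559e-06, 7.367572885903746e-07,
      -3.2054419133447798e-06, -1.6312699734552807e-05, -6.5543059305751491e-05, -0.00060115023435160925,
      0.002704672124643725, 0.0022025341009110021, -0.006045814097323304, -0.0063877183184971563,
      0.011061496392513451, 0.015270015130934803, -0.017423434103729693, -0.032130793990211758,
      0.024348745906078023, 0.063739024322801596, -0.030655091960824263, -0.13284520043622938,
      0.035087555656258346, 0.44459300275757724, -0.74458559231880628, 0.44459300275757724,
      0.035087555656258346, -0.13284520043622938, -0.030655091960824263, 0.063739024322801596,
      0.024348745906078023, -0.032130793990211758, -0.017423434103729693, 0.015270015130934803,
      0.011061496392513451, -0.0063877183184971563, -0.006045814097323304, 0.0022025341009110021,
      0.002704672124643725, -0.00060115023435160925, -6.5543059305751491e-05, -1.6312699734552807e-05,
      -3.2054419133447798e-06, 7.367572885903746e-07, 1.4895492164971559e-06, 1.1307947017916706e-06,
      5.5063405652522782e-07, 1.1783004497663934e-07, -8.2006806503864813e-08, -1.0866516536735883e-07,
      -6.0669757413511352e-08, -1.0798819539621958e-08, 1.111944952595278e-08, 8.519459636796214e-09,
      1.0099999569414229e-12, 0),
    rec_lo = c(-1.0099999569414229e-12, 8.519459636796214e-09, -1.111944952595278e-08, -1.0798819539621958e-08,
      6.0669757413511352e-08, -1.0866516536735883e-07, 8.2006806503864813e-08, 1.1783004497663934e-07,
      -5.5063405652522782e-07, 1.1307947017916706e-06, -1.4895492164971559e-06, 7.367572885903746e-07,
      3.2054419133447798e-06, -1.6312699734552807e-05, 6.5543059305751491e-05, -0.00060115023435160925,
      -0.002704672124643725, 0.0022025341009110021, 0.006045814097323304, -0.0063877183184971563,
      -0.011061496392513451, 0.015270015130934803, 0.017423434103729693, -0.032130793990211758,
      -0.024348745906078023, 0.063739024322801596, 0.030655091960824263, -0.13284520043622938,
      -0.035087555656258346, 0.44459300275757724, 0.74458559231880628, 0.44459300275757724,
      -0.035087555656258346, -0.13284520043622938, 0.030655091960824263, 0.063739024322801596,
      -0.024348745906078023, -0.032130793990211758, 0.017423434103729693, 0.015270015130934803,
      -0.011061496392513451, -0.0063877183184971563, 0.006045814097323304, 0.0022025341009110021,
      -0.002704672124643725, -0.00060115023435160925, 6.5543059305751491e-05, -1.6312699734552807e-05,
      3.2054419133447798e-06, 7.367572885903746e-07, -1.4895492164971559e-06, 1.1307947017916706e-06,
      -5.5063405652522782e-07, 1.1783004497663934e-07, 8.2006806503864813e-08, -1.0866516536735883e-07,
      6.0669757413511352e-08, -1.0798819539621958e-08, -1.111944952595278e-08, 8.519459636796214e-09,
      -1.0099999569414229e-12, 0),
    rec_hi = c(0, 1.0099999569414229e-12, 8.519459636796214e-09, 1.111944952595278e-08,
      -1.0798819539621958e-08, -6.0669757413511352e-08, -1.0866516536735883e-07, -8.2006806503864813e-08,
      1.1783004497663934e-07, 5.5063405652522782e-07, 1.1307947017916706e-06, 1.4895492164971559e-06,
      7.367572885903746e-07, -3.2054419133447798e-06, -1.6312699734552807e-05, -6.5543059305751491e-05,
      -0.00060115023435160925, 0.002704672124643725, 0.0022025341009110021, -0.006045814097323304,
      -0.0063877183184971563, 0.011061496392513451, 0.015270015130934803, -0.017423434103729693,
      -0.032130793990211758, 0.024348745906078023, 0.063739024322801596, -0.030655091960824263,
      -0.13284520043622938, 0.035087555656258346, 0.44459300275757724, -0.74458559231880628,
      0.44459300275757724, 0.035087555656258346, -0.13284520043622938, -0.030655091960824263,
      0.063739024322801596, 0.024348745906078023, -0.032130793990211758, -0.017423434103729693,
      0.015270015130934803, 0.011061496392513451, -0.0063877183184971563, -0.006045814097323304,
      0.0022025341009110021, 0.002704672124643725, -0.00060115023435160925, -6.5543059305751491e-05,
      -1.6312699734552807e-05, -3.2054419133447798e-06, 7.367572885903746e-07, 1.4895492164971559e-06,
      1.1307947017916706e-06, 5.5063405652522782e-07, 1.1783004497663934e-07, -8.2006806503864813e-08,
      -1.0866516536735883e-07, -6.0669757413511352e-08, -1.0798819539621958e-08, 1.111944952595278e-08,
      8.519459636796214e-09, 1.0099999569414229e-12)),
  "coif4" = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.2338854312787192e-05,
      -0.00025997433712225682, -0.00058902022463321654, 0.0012665610789256603, 0.0037514346971460866,
      -0.0056582838001308835, -0.015211728187697211, 0.025082253337949612, 0.039334422605589149,
      -0.096220424535952642, -0.066627472366817167, 0.43438603311435653, 0.78223893442428261,
      0.41530842700068227, -0.056077319603569258, -0.081266710249193727, 0.02668230466960483,
      0.016068947131575029, -0.0073461679362680507, -0.001629492425226786, 0.00089231390253700297),
    dec_hi = c(-0.00089231390253700297, -0.001629492425226786, 0.0073461679362680507, 0.016068947131575029,
      -0.02668230466960483, -0.081266710249193727, 0.056077319603569258, 0.41530842700068227,
      -0.78223893442428261, 0.43438603311435653, 0.066627472366817167, -0.096220424535952642,
      -0.039334422605589149, 0.025082253337949612, 0.015211728187697211, -0.0056582838001308835,
      -0.0037514346971460866, 0.0012665610789256603, 0.00058902022463321654, -0.00025997433712225682,
      -6.2338854312787192e-05, 3.1229861599195265e-05, 3.259647940030751e-06, -1.7849909144933469e-06),
    rec_lo = c(0.00089231390253700297, -0.001629492425226786, -0.0073461679362680507, 0.016068947131575029,
      0.02668230466960483, -0.081266710249193727, -0.056077319603569258, 0.41530842700068227,
      0.78223893442428261, 0.43438603311435653, -0.066627472366817167, -0.096220424535952642,
      0.039334422605589149, 0.025082253337949612, -0.015211728187697211, -0.0056582838001308835,
      0.0037514346971460866, 0.0012665610789256603, -0.00058902022463321654, -0.00025997433712225682,
      6.2338854312787192e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    rec_hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05, -6.2338854312787192e-05,
      -0.00025997433712225682, 0.00058902022463321654, 0.0012665610789256603, -0.0037514346971460866,
      -0.0056582838001308835, 0.015211728187697211, 0.025082253337949612, -0.039334422605589149,
      -0.096220424535952642, 0.066627472366817167, 0.43438603311435653, -0.78223893442428261,
      0.41530842700068227, 0.056077319603569258, -0.081266710249193727, -0.02668230466960483,
      0.016068947131575029, 0.0073461679362680507, -0.001629492425226786, -0.00089231390253700297))
)

#' List the wavelet bases available for the packet transform
#'
#' Returns the names of the built-in two-channel filter banks.  The set
#' covers the eleven candidate bases considered for theta/alpha oscillation
#' extraction (symlets, Daubechies, coiflets, biorthogonal spline pairs and
#' their duals, and the discrete Meyer wavelet).
#'
#' @return Character vector of basis names, e.g. \code{"rbio3.7"}.
#' @export
#' @examples
#' wp_bases()
wp_bases <- function() names(.wp_filter_bank)

# Retrieve a filter bank; errors on unknown basis names.
wp_filters <- function(basis) {
  if (!is.character(basis) || length(basis) != 1L || !basis %in% names(.wp_filter_bank))
    stop("unknown wavelet basis '", basis, "'; see wp_bases()", call. = FALSE)
  .wp_filter_bank[[basis]]
}
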