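# Surrogate default trait sampling ranges (synthetic; calibrated in-house,
# see the methods vignette). Masses are sampled log-uniformly, all other
# traits uniformly.
M_Max: [10.0, 1000.0]        # maximum mass, g
M_Mat_frac: [0.25, 0.5]      # mass at maturity as fraction of M_Max
n_RPot: [0.14, 0.65]          # potential recruits per mature individual per year
D_K: [0.45, 1.2]              # negative-exponential dispersal factor, 1/m
D_KAs: [1.0, 3.0]            # downward dispersal asymmetry multiplier
I_Min: [1.0, 300.0]         # lower light niche limit, umol m-2 s-1
I_width: [300.0, 900.0]      # niche width I_Max - I_Min, umol m-2 s-1
A_Mat_jitter: [0.8, 1.25]    # multiplicative jitter on the maturity correlation
A_Mat: [2.0, 40.0]           # clamp range for age at maturity, years
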