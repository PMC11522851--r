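metric,auc,auc_ci_lo,auc_ci_hi,cutoff,direction,sensitivity_pct,specificity_pct,youden_printed,sum_convention_exact
mo_spo2,0.770,0.676,0.863,85.5,below,66.7,76.0,1.427,TRUE
ov_spo2,0.796,0.699,0.879,82.7,below,79.0,70.8,1.497,FALSE
hr_over_spo2,0.694,0.573,0.815,0.817,above,57.9,76.0,1.406,FALSE
variance,0.726,0.598,0.855,6.056,above,58.0,87.2,1.451,FALSE
total_desaturations,0.753,0.637,0.868,285.0,above,57.9,85.4,1.433,TRUE
desaturation_duration_s,0.716,0.582,0.851,18.3,below,57.9,82.6,1.405,TRUE
odi_per_h,0.756,0.637,0.875,34.7,above,57.9,86.8,1.447,TRUE
hypoxic_burden,0.798,0.708,0.888,119.6,above,94.7,57.6,1.523,TRUE
tst80_pct,0.782,0.676,0.889,2.07,above,80.0,66.3,1.499,FALSE
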