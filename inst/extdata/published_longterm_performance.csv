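# Published mean long-term validation performance of mobile and
# transfer-learning LUR models (published campaign; NO2 82 sites,
# UFP 17 sites). Used to recompute the improvement-percentage table.
pollutant,model,metric,value
NO2,slr,nmae,0.19
NO2,slr,nrmse,0.23
NO2,slr,r2,0.49
NO2,rf_lur,nmae,0.29
NO2,rf_lur,nrmse,0.38
NO2,rf_lur,r2,0.53
NO2,prior_rf,nmae,0.24
NO2,prior_rf,nrmse,0.31
NO2,prior_rf,r2,0.62
NO2,tradaboost,nmae,0.13
NO2,tradaboost,nrmse,0.18
NO2,tradaboost,r2,0.54
UFP,slr,nmae,0.22
UFP,slr,nrmse,0.27
UFP,slr,r2,0.20
UFP,rf_lur,nmae,0.26
UFP,rf_lur,nrmse,0.35
UFP,rf_lur,r2,0.15
UFP,prior_rf,nmae,0.19
UFP,prior_rf,nrmse,0.25
UFP,prior_rf,r2,0.28
UFP,tradaboost,nmae,0.21
UFP,tradaboost,nrmse,0.25
UFP,tradaboost,r2,0.25
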