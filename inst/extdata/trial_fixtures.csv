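fixture,id,estimate,ci_lower,ci_upper,ci_level,p_onesided,source
respire_14d,RESPIRE 1,-0.49,-0.85,-0.13,0.95,0.00351,"RESPIRE trials, 14-day group, first trial row (log rate ratio, 95% CI, one-sided p)"
respire_14d,RESPIRE 2,-0.18,-0.53,0.16,0.95,0.14400,"RESPIRE trials, 14-day group, second trial row"
respire_28d,RESPIRE 1,-0.02,-0.39,0.35,0.95,0.45699,"RESPIRE trials, 28-day group, first trial row"
respire_28d,RESPIRE 2,-0.60,-0.96,-0.23,0.95,0.00064,"RESPIRE trials, 28-day group, second trial row"
respire_all4,RESPIRE 1 (14d),-0.49,-0.85,-0.13,0.95,0.00351,"RESPIRE trials, 14-day group, first trial row"
respire_all4,RESPIRE 2 (14d),-0.18,-0.53,0.16,0.95,0.14400,"RESPIRE trials, 14-day group, second trial row"
respire_all4,RESPIRE 1 (28d),-0.02,-0.39,0.35,0.95,0.45699,"RESPIRE trials, 28-day group, first trial row"
respire_all4,RESPIRE 2 (28d),-0.60,-0.96,-0.23,0.95,0.00064,"RESPIRE trials, 28-day group, second trial row"
orbit_primary,ORBIT 3,-0.01,-0.34,0.32,0.95,0.47636,"ORBIT trials, primary endpoint (log hazard ratio, time to first exacerbation), ORBIT 3 row"
orbit_primary,ORBIT 4,-0.33,-0.63,-0.03,0.95,0.01657,"ORBIT trials, primary endpoint, ORBIT 4 row"
orbit_secondary,ORBIT 3,-0.16,-0.43,0.11,0.95,0.12083,"ORBIT trials, secondary endpoint (log rate ratio, exacerbation frequency), ORBIT 3 row"
orbit_secondary,ORBIT 4,-0.46,-0.73,-0.19,0.95,0.00036,"ORBIT trials, secondary endpoint, ORBIT 4 row"
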