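trial,arm,role,timepoint,scheduled_age_days,mean_age_days,n,metric,value,ci_low,ci_high,proportion_female,mode
synthetic_egg,control,control,baseline,365,365,300,stature,65.1167276067516,64.8206842564244,65.4127709570788,0.5,length
synthetic_egg,control,control,endline,545,545,300,stature,70.1320321769317,69.8082527392829,70.4558116145805,0.5,length
synthetic_egg,intervention,intervention,baseline,365,365,300,stature,64.9644996166653,64.6684562663382,65.2605429669925,0.5,length
synthetic_egg,intervention,intervention,endline,545,545,300,stature,72.6202759780842,72.2964965404354,72.944055415733,0.5,length
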