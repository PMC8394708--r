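attribute,group,statistic,value
mobility,all,n_problem,83
mobility,all,proportion,0.374
mobility,iFOBT,n_problem,60
mobility,iFOBT,proportion,0.366
mobility,genetic_testing,n_problem,23
mobility,genetic_testing,proportion,0.397
self_care,all,n_problem,67
self_care,all,proportion,0.302
self_care,iFOBT,n_problem,49
self_care,iFOBT,proportion,0.299
self_care,genetic_testing,n_problem,18
self_care,genetic_testing,proportion,0.310
usual_activities,all,n_problem,86
usual_activities,all,proportion,0.387
usual_activities,iFOBT,n_problem,67
usual_activities,iFOBT,proportion,0.409
usual_activities,genetic_testing,n_problem,19
usual_activities,genetic_testing,proportion,0.328
pain_discomfort,all,n_problem,114
pain_discomfort,all,proportion,0.514
pain_discomfort,iFOBT,n_problem,71
pain_discomfort,iFOBT,proportion,0.433
pain_discomfort,genetic_testing,n_problem,43
pain_discomfort,genetic_testing,proportion,0.741
anxiety_depression,all,n_problem,98
anxiety_depression,all,proportion,0.441
anxiety_depression,iFOBT,n_problem,70
anxiety_depression,iFOBT,proportion,0.427
anxiety_depression,genetic_testing,n_problem,28
anxiety_depression,genetic_testing,proportion,0.483
utility,all,mean,0.787
utility,all,sd,0.273
utility,all,median,0.861
utility,iFOBT,mean,0.801
utility,iFOBT,sd,0.264
utility,iFOBT,median,0.890
utility,genetic_testing,mean,0.744
utility,genetic_testing,sd,0.296
utility,genetic_testing,median,0.834
vas,all,mean,73.58
vas,all,sd,18.47
vas,all,median,78.20
vas,iFOBT,mean,73.10
vas,iFOBT,sd,17.28
vas,iFOBT,median,77.50
vas,genetic_testing,mean,74.93
vas,genetic_testing,sd,21.59
vas,genetic_testing,median,80.00
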