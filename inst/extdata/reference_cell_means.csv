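# Published cell means (mean, sd) for the transgenerational UVB exposure
# experiment on a rock-pool Philodina bdelloid: lifespan (days), net
# reproductive rate R0, generation time T (days), intrinsic rate of increase
# r (per day), by generation (F1/F5) x feeding (fed/starved, plus the
# published per-generation "mean" rows) x UVB treatment (control 0, low 1.3,
# mid 3.7, high 5.0 W/m2). The F5 high-UVB cells are ND (no cohorts: too few
# F4 offspring) and carry empty values. Values transcribed at printed
# precision; the F1 low "mean" lifespan row is 55.7 as printed, although the
# unweighted mean of the printed fed and starved cells is 57.8.
metric,generation,feeding,treatment,mean,sd
lifespan,F1,fed,control,32.1,9.8
lifespan,F1,fed,low,69.6,35.0
lifespan,F1,fed,mid,38.4,6.4
lifespan,F1,fed,high,21.5,9.0
lifespan,F1,starved,control,24.5,5.1
lifespan,F1,starved,low,46.0,7.8
lifespan,F1,starved,mid,33.4,1.0
lifespan,F1,starved,high,20.7,6.2
lifespan,F1,mean,control,28.3,5.4
lifespan,F1,mean,low,55.7,14.1
lifespan,F1,mean,mid,35.9,4.9
lifespan,F1,mean,high,21.1,4.5
lifespan,F5,fed,control,39.1,11.1
lifespan,F5,fed,low,58.7,25.1
lifespan,F5,fed,mid,55.9,21.7
lifespan,F5,fed,high,,
lifespan,F5,starved,control,22.1,2.5
lifespan,F5,starved,low,40.5,15.3
lifespan,F5,starved,mid,39.8,4.3
lifespan,F5,starved,high,,
lifespan,F5,mean,control,30.6,10.2
lifespan,F5,mean,low,49.6,14.2
lifespan,F5,mean,mid,47.8,10.3
lifespan,F5,mean,high,,
R0,F1,fed,control,9.7,0.3
R0,F1,fed,low,32.3,1.1
R0,F1,fed,mid,29.5,3.9
R0,F1,fed,high,8.6,1.1
R0,F1,starved,control,4.0,1.8
R0,F1,starved,low,11.2,1.3
R0,F1,starved,mid,4.9,0.8
R0,F1,starved,high,0.1,0.1
R0,F1,mean,control,6.9,3.3
R0,F1,mean,low,21.7,11.4
R0,F1,mean,mid,17.2,14.1
R0,F1,mean,high,4.3,4.8
R0,F5,fed,control,26.0,2.6
R0,F5,fed,low,31.0,0.9
R0,F5,fed,mid,34.4,1.0
R0,F5,fed,high,,
R0,F5,starved,control,11.4,3.3
R0,F5,starved,low,24.3,12.3
R0,F5,starved,mid,20.5,2.3
R0,F5,starved,high,,
R0,F5,mean,control,13.6,13.9
R0,F5,mean,low,17.4,14.4
R0,F5,mean,mid,19.1,16.2
R0,F5,mean,high,,
T,F1,fed,control,9.7,0.5
T,F1,fed,low,19.8,3.6
T,F1,fed,mid,16.4,1.5
T,F1,fed,high,7.0,3.7
T,F1,starved,control,12.6,5.2
T,F1,starved,low,15.6,1.9
T,F1,starved,mid,16.2,0.8
T,F1,starved,high,8.0,2.8
T,F1,mean,control,11.2,3.7
T,F1,mean,low,17.7,2.9
T,F1,mean,mid,16.3,1.1
T,F1,mean,high,7.4,3.0
T,F5,fed,control,12.3,2.1
T,F5,fed,low,17.3,2.0
T,F5,fed,mid,18.1,1.3
T,F5,fed,high,,
T,F5,starved,control,1.1,0.5
T,F5,starved,low,3.9,2.5
T,F5,starved,mid,3.9,2.5
T,F5,starved,high,,
T,F5,mean,control,11.8,2.5
T,F5,mean,low,20.8,10.8
T,F5,mean,mid,19.4,2.3
T,F5,mean,high,,
r,F1,fed,control,0.23,0.01
r,F1,fed,low,0.18,0.01
r,F1,fed,mid,0.21,0.01
r,F1,fed,high,0.35,0.08
r,F1,starved,control,0.15,0.08
r,F1,starved,low,0.14,0.02
r,F1,starved,mid,0.10,0.01
r,F1,starved,high,-0.26,0.37
r,F1,mean,control,0.18,0.08
r,F1,mean,low,0.17,0.02
r,F1,mean,mid,0.15,0.06
r,F1,mean,high,0.11,0.36
r,F5,fed,control,0.27,0.02
r,F5,fed,low,0.20,0.01
r,F5,fed,mid,0.20,0.01
r,F5,fed,high,,
r,F5,starved,control,0.01,0.05
r,F5,starved,low,0.02,0.11
r,F5,starved,mid,0.05,0.06
r,F5,starved,high,,
r,F5,mean,control,0.14,0.15
r,F5,mean,low,0.11,0.12
r,F5,mean,mid,0.13,0.08
r,F5,mean,high,,
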