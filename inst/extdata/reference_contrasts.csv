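# Published percent-change contrasts that reproduce exactly (at printed
# precision) from the printed cell means in reference_cell_means.csv.
# scope records which rows the published value is computed on: "mean" = the
# per-generation fed/starved mean rows, "fed" = fed cells only (the
# published high-UVB lifespan contrast uses the fed scope). Published
# contrasts that do NOT reproduce from any printed row pair (F5-vs-F1
# lifespan low/mid, and the F5-vs-F1 mid R0 value printed as 11.1 where the
# printed means give 11.0) are deliberately absent.
metric,family,generation,treatment,scope,published_pct
lifespan,vs_control,F1,low,mean,96.8
lifespan,vs_control,F1,mid,mean,26.9
lifespan,vs_control,F1,high,fed,-33.0
lifespan,vs_control,F5,low,mean,62.1
lifespan,vs_control,F5,mid,mean,56.2
lifespan,f5_vs_f1,F5,control,mean,8.1
R0,vs_control,F1,low,mean,214.5
R0,vs_control,F1,mid,mean,149.3
R0,vs_control,F1,high,mean,-37.7
R0,vs_control,F5,mid,mean,40.4
R0,f5_vs_f1,F5,control,mean,97.1
R0,f5_vs_f1,F5,low,mean,-19.8
T,vs_control,F1,low,mean,58.0
T,vs_control,F1,mid,mean,45.5
T,vs_control,F1,high,mean,-33.9
T,vs_control,F5,low,mean,76.3
T,vs_control,F5,mid,mean,64.4
T,f5_vs_f1,F5,mid,mean,19.0
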