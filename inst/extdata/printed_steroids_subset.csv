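site,status,depth_cm,replicate,compound_class,compound,concentration
AV-D,degraded_drained,10,1,steroid,brassicasterol,71
AV-D,degraded_drained,10,1,steroid,campesterol,342
AV-D,degraded_drained,10,1,steroid,stigmasterol,308
AV-D,degraded_drained,10,1,steroid,sitosterol,895
AV-D,degraded_drained,10,1,steroid,stigmastanol,208
AV-D,degraded_drained,10,1,steroid,lanosterol,ND
AV-D,degraded_drained,10,1,steroid,ergosterol,ND
AV-D,degraded_drained,30,1,steroid,brassicasterol,18
AV-D,degraded_drained,30,1,steroid,campesterol,11
AV-D,degraded_drained,30,1,steroid,stigmasterol,19
AV-D,degraded_drained,30,1,steroid,sitosterol,573
AV-D,degraded_drained,30,1,steroid,stigmastanol,171
AV-D,degraded_drained,80,1,steroid,brassicasterol,13
AV-D,degraded_drained,80,1,steroid,campesterol,160
AV-D,degraded_drained,80,1,steroid,stigmasterol,84
AV-D,degraded_drained,80,1,steroid,sitosterol,429
AV-D,degraded_drained,80,1,steroid,stigmastanol,150
AV-D,degraded_drained,80,1,steroid,lanosterol,88
PU-N,natural,30,1,steroid,ergosterol,82
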