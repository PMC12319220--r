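stratum,ref_cat,new_cat,count
nonevent,1,1,36
nonevent,1,2,1
nonevent,1,3,2
nonevent,1,4,0
nonevent,2,1,23
nonevent,2,2,11
nonevent,2,3,2
nonevent,2,4,0
nonevent,3,1,26
nonevent,3,2,4
nonevent,3,3,1
nonevent,3,4,3
nonevent,4,1,7
nonevent,4,2,2
nonevent,4,3,4
nonevent,4,4,14
event,1,1,1
event,1,2,0
event,1,3,1
event,1,4,0
event,2,1,3
event,2,2,0
event,2,3,1
event,2,4,0
event,3,1,2
event,3,2,2
event,3,3,1
event,3,4,2
event,4,1,1
event,4,2,0
event,4,3,3
event,4,4,10
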