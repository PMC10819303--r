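condition,sample,channel,square,count
no_field,1,A,1,47
no_field,1,A,2,53
no_field,1,A,3,40
no_field,1,A,4,49
no_field,1,B,1,48
no_field,1,B,2,50
no_field,1,B,3,47
no_field,1,B,4,57
no_field,2,A,1,42
no_field,2,A,2,54
no_field,2,A,3,62
no_field,2,A,4,45
no_field,2,B,1,56
no_field,2,B,2,43
no_field,2,B,3,58
no_field,2,B,4,63
blocking,1,A,1,23
blocking,1,A,2,16
blocking,1,A,3,16
blocking,1,A,4,17
blocking,1,B,1,88
blocking,1,B,2,44
blocking,1,B,3,64
blocking,1,B,4,72
blocking,2,A,1,19
blocking,2,A,2,14
blocking,2,A,3,20
blocking,2,A,4,31
blocking,2,B,1,68
blocking,2,B,2,79
blocking,2,B,3,85
blocking,2,B,4,73
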