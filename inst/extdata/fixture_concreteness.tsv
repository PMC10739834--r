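apple	5.00
car	4.90
dog	4.85
table	4.90
water	5.00
house	4.90
tree	5.00
chair	4.98
bread	4.92
train	4.87
book	4.90
coffee	4.95
beach	4.75
ticket	4.70
blanket	4.90
stadium	4.60
guitar	4.95
bicycle	4.90
garden	4.70
kitchen	4.80
window	4.85
mountain	4.80
river	4.85
shoe	4.96
phone	4.90
door	4.90
lamp	4.90
box	4.90
street	4.70
bag	4.90
idea	1.61
freedom	1.72
justice	1.45
belief	1.19
theory	1.53
truth	1.96
honesty	1.55
opinion	1.62
reason	1.78
concept	1.40
morality	1.40
policy	2.00
value	1.98
principle	1.30
logic	1.60
thought	2.10
doubt	1.80
hope	1.60
chance	1.70
purpose	1.50
plan	2.55
trip	3.30
meeting	3.40
dinner	4.40
swim	4.10
concert	4.20
story	2.90
friend	4.10
family	3.90
weekend	3.10
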