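word,polarity,subjectivity,intensity
best,1.0,0.3,1.0
better,0.5,0.5,1.0
good,0.7,0.6,1.0
great,0.8,0.75,1.0
excellent,1.0,1.0,1.0
wonderful,1.0,1.0,1.0
awesome,1.0,1.0,1.0
amazing,0.6,0.9,1.0
outstanding,0.8,0.9,1.0
superb,0.9,0.9,1.0
nice,0.6,1.0,1.0
fine,0.4166,0.5,1.0
available,0.4,0.4,1.0
helpful,0.4,0.5,1.0
supportive,0.4,0.5,1.0
friendly,0.5,0.6,1.0
welcoming,0.5,0.6,1.0
caring,0.5,0.6,1.0
kind,0.6,0.9,1.0
gentle,0.4,0.65,1.0
professional,0.1,0.3,1.0
reliable,0.5,0.6,1.0
trustworthy,0.6,0.7,1.0
accurate,0.4,0.6,1.0
effective,0.5,0.6,1.0
beneficial,0.5,0.6,1.0
safe,0.5,0.5,1.0
healthy,0.5,0.55,1.0
clean,0.3666,0.75,1.0
comfortable,0.5,0.7,1.0
convenient,0.4,0.6,1.0
affordable,0.3,0.5,1.0
free,0.4,0.8,1.0
easy,0.4333,0.8333,1.0
quick,0.3333,0.5416,1.0
prompt,0.3,0.4,1.0
happy,0.8,1.0,1.0
glad,0.5,1.0,1.0
proud,0.5,0.7,1.0
calm,0.3,0.55,1.0
positive,0.2272,0.5545,1.0
painless,0.3,0.6,1.0
harmless,0.3,0.5,1.0
recommended,0.3,0.5,1.0
important,0.4,1.0,1.0
new,0.1363,0.4545,1.0
modern,0.2,0.4,1.0
clear,0.1,0.3833,1.0
simple,0.0,0.3571,1.0
mild,0.1,0.4,1.0
only,0.0,1.0,1.0
certain,0.2142,0.5714,1.0
private,0.0,0.4,1.0
confidential,0.0,0.3,1.0
current,0.0,0.4,1.0
bad,-0.7,0.6666,1.0
worse,-0.4,0.6,1.0
worst,-1.0,1.0,1.0
terrible,-1.0,1.0,1.0
horrible,-1.0,1.0,1.0
awful,-1.0,1.0,1.0
atrocious,-0.39,0.8,1.0
dreadful,-0.9,0.9,1.0
poor,-0.4,0.6,1.0
sad,-0.5,1.0,1.0
unhappy,-0.6,0.8,1.0
sick,-0.7142,0.8571,1.0
painful,-0.7,0.9,1.0
dangerous,-0.6,0.9,1.0
risky,-0.5,0.7,1.0
harmful,-0.6,0.7,1.0
severe,-0.4,0.7,1.0
serious,-0.3,0.6,1.0
difficult,-0.5,1.0,1.0
hard,-0.2916,0.5416,1.0
complicated,-0.3,0.6,1.0
confusing,-0.4,0.7,1.0
unreliable,-0.5,0.6,1.0
inaccurate,-0.4,0.6,1.0
outdated,-0.3,0.4,1.0
inconvenient,-0.4,0.6,1.0
uncomfortable,-0.5,0.7,1.0
unsafe,-0.5,0.5,1.0
rude,-0.6,0.9,1.0
dirty,-0.6,0.8,1.0
expensive,-0.2,0.5,1.0
slow,-0.3,0.4,1.0
negative,-0.3,0.6,1.0
worried,-0.3,0.6,1.0
anxious,-0.4,0.8,1.0
very,0.2,0.3,1.3
really,0.2,0.2,1.3
extremely,0.25,0.75,1.5
highly,0.2,0.5,1.4
quite,0.0,0.5,1.1
slightly,0.0,0.2,0.8
somewhat,0.0,0.35,0.9
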