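# Default structural-tendency scheme in file form
P	disorder-promoting
E	disorder-promoting
S	disorder-promoting
Q	disorder-promoting
K	disorder-promoting
A	disorder-promoting
G	disorder-promoting
M	order-promoting
N	order-promoting
V	order-promoting
H	order-promoting
L	order-promoting
F	order-promoting
Y	order-promoting
I	order-promoting
W	order-promoting
C	order-promoting
D	disorder-neutral
T	disorder-neutral
R	disorder-neutral
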