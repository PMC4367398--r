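# Parametric L-system for the cherry tomato variety.
# Differs from the ordinary variety in where flowers grow: the cherry
# tomato may carry leaves and flowers on the same branch, so full-fledged
# branches (type 2) bear both, and flower branches (type 3) also carry a
# leaf near their base.
A(i,j) : i != nc && choice(i+1) == 1 -> /F(0)[&B(1,0)]A(i+1,j+1)
A(i,j) : i != nc && choice(i+1) == 2 -> /F(0)[&B(2,0)]A(i+1,j+1)
A(i,j) : i != nc && choice(i+1) == 3 -> /F(0)[&B(3,0)]A(i+1,j+1)
A(i,j) : i != nc && choice(i+1) == 4 -> F(0)[+l(0)][-l(0)]y(0)
A(i,j) : i != nc && choice(i+1) == 5 -> F(0)[+P(0)][-P(0)]y(0)
A(i,j) : i == nc -> y(0)
B(t,a) : t == 1 -> C(0)
B(t,a) : t == 2 -> D(0)
B(t,a) : t == 3 -> h(0)
C(a) :  -> S(0)[+L(r)]
# Type 2: leaves and flowers on the same branch.
D(a) : a == 0 -> f(0)[#L(0)][&P(0)]D(1)
D(a) : a == 1 -> f(0)[#L(0)][&P(0)]D(2)
D(a) : a == 2 -> f(0)[#l(0)]
# Type 3: flower branch with a basal leaf.
h(a) : a == 0 -> h(1)[#L(0)][&P(0)]
h(a) : a == 1 -> h(2)[&P(0)]
P(age) : age == 1 -> P(r)[H(0)]
H(age) : age == 2 -> G(0)
L(age) : age == r -> L(3)][-L(0)
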