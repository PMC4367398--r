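# Parametric L-system for the ordinary greenhouse tomato variety.
# Leaves and flowers grow on separate branches: full-fledged branches (type
# 2) bear leaves only; flower branches (type 3) bear flower stalks only.
#
# Main-stem apex A(i, j): each growth stage adds one internode (with a small
# main-stem curvature '/') and the next lateral branch from the plant's
# choice string; i traverses the choice string, j counts main-stem growth.
A(i,j) : i != nc && choice(i+1) == 1 -> /F(0)[&B(1,0)]A(i+1,j+1)
A(i,j) : i != nc && choice(i+1) == 2 -> /F(0)[&B(2,0)]A(i+1,j+1)
A(i,j) : i != nc && choice(i+1) == 3 -> /F(0)[&B(3,0)]A(i+1,j+1)
# Terminal forms atop the main stem: leaves only (4) or flowers (5).
A(i,j) : i != nc && choice(i+1) == 4 -> F(0)[+l(0)][-l(0)]y(0)
A(i,j) : i != nc && choice(i+1) == 5 -> F(0)[+P(0)][-P(0)]y(0)
A(i,j) : i == nc -> y(0)
# Pending lateral branch B(t, a) dispatches on its branch form.
B(t,a) : t == 1 -> C(0)
B(t,a) : t == 2 -> D(0)
B(t,a) : t == 3 -> h(0)
# Type 1: a short shoot that is itself a compound leaf.
C(a) :  -> S(0)[+L(r)]
# Type 2: full-fledged branch, leaves along it and a single leaf at the end.
D(a) : a == 0 -> f(0)[#L(0)]D(1)
D(a) : a == 1 -> f(0)[#L(0)]D(2)
D(a) : a == 2 -> f(0)[#l(0)]
# Type 3: flower branch; stalks appear while the branch elongates.
h(a) : a == 0 -> h(1)[&P(0)]
h(a) : a == 1 -> h(2)[&P(0)]
# A flower stalk matures and bears a flower; as soon as the flower withers
# a fruit begins to grow at the same place on the branch.
P(age) : age == 1 -> P(r)[H(0)]
H(age) : age == 2 -> G(0)
# A stable side leaf bifurcates into two leaves at the next recursion.
L(age) : age == r -> L(3)][-L(0)
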