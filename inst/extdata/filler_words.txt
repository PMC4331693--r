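the
of
and
in
to
a
is
was
were
for
with
on
by
as
that
this
study
results
effects
analysis
treatment
cells
patients
levels
increased
decreased
observed
significant
compared
control
group
groups
method
methods
using
used
showed
shown
found
response
activity
expression
protein
gene
role
effect
model
data
between
during
after
before
under
conditions
present
report
novel
approach
evaluated
measured
determined
performed
obtained
induced
mediated
associated
related
potential
important
clinical
experimental
samples
tissue
plasma
serum
blood
liver
brain
kidney
lung
heart
muscle
rats
mice
human
animal
vitro
vivo
dose
doses
concentration
concentrations
exposure
administration
injection
oral
daily
weekly
baseline
followup
outcome
outcomes
risk
factor
factors
pathway
pathways
signaling
receptor
receptors
binding
inhibition
activation
regulation
function
functions
mechanism
mechanisms
structure
properties
synthesis
production
formation
degradation
metabolism
uptake
release
transport
growth
proliferation
apoptosis
differentiation
viability
toxicity
damage
stress
inflammation
oxidative
cellular
molecular
biological
chemical
physical
thermal
stability
solubility
affinity
selectivity
efficacy
safety
profile
assay
assays
spectroscopy
chromatography
microscopy
imaging
measurement
detection
identification
characterization
purification
isolation
extraction
preparation
development
application
applications
evaluation
investigation
comparison
correlation
association
relationship
difference
differences
change
changes
increase
decrease
reduction
improvement
enhancement
modulation
variation
range
values
mean
median
total
relative
respective
various
several
further
however
therefore
moreover
whereas
although
among
within
across
through
against
toward
higher
lower
greater
smaller
similar
different
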