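# Default APQI indicator configuration.
#
# One entry per indication: ICPC-2 code, eligibility window (age in completed
# years, bounds inclusive under the default age_boundary option; sex
# restriction or null), the guideline-recommended antibiotic set as ATC
# prefixes (any level; a prescription is "recommended" when its ATC code
# starts with any listed prefix), and the acceptable ranges for the three
# indicator values in percent:
#   range_a : % of eligible patients prescribed an antibiotic
#   range_b : % of treated patients receiving a recommended antibiotic
#   range_c : % of treated patients receiving quinolones
#
# Recommended sets follow Belgian first-line guidance (BAPCOC): narrow-
# spectrum penicillin (J01CE) for tonsillitis and upper RTI, amoxicillin
# (J01CA04) for otitis media / sinusitis / bronchitis / pneumonia / dental
# infection, nitrofuran derivatives (J01XE) for cystitis, beta-lactamase-
# resistant penicillins (J01CF) for erysipelas. They are data, not code:
# edit this file (or pass your own to apqi_config()) to change them.
#
# Entries marked proposed: true carry acceptable ranges proposed for
# out-of-hours care rather than established ESAC ranges.

options:
  age_boundary: inclusive   # "older than N years" counts age >= N ("strict": > N)
  bc_denominator: treated   # b and c as % of antibiotic-treated ("eligible": % of eligible)

indicators:
  - icpc: H71
    label: "Acute otitis media / myringitis"
    min_age: 2
    max_age: ~
    sex: ~
    recommended: ["J01CA04"]
    range_a: [0, 20]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: R74
    label: "Acute upper respiratory tract infection"
    min_age: 1
    max_age: ~
    sex: ~
    recommended: ["J01CE"]
    range_a: [0, 20]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: R75
    label: "Acute / chronic sinusitis"
    min_age: 18
    max_age: ~
    sex: ~
    recommended: ["J01CA04"]
    range_a: [0, 20]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: R76
    label: "Acute tonsillitis"
    min_age: 1
    max_age: ~
    sex: ~
    recommended: ["J01CE"]
    range_a: [0, 20]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: R78
    label: "Acute bronchitis / bronchiolitis"
    min_age: 18
    max_age: 75
    sex: ~
    recommended: ["J01CA04"]
    range_a: [0, 30]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: R81
    label: "Pneumonia"
    min_age: 18
    max_age: 65
    sex: ~
    recommended: ["J01CA04"]
    range_a: [80, 100]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: U71
    label: "Cystitis / other urinary infection"
    min_age: 18
    max_age: ~
    sex: "F"
    recommended: ["J01XE"]
    range_a: [80, 100]
    range_b: [80, 100]
    range_c: [0, 5]
  - icpc: S76
    label: "Erysipelas"
    min_age: 1
    max_age: ~
    sex: ~
    recommended: ["J01CF"]
    range_a: [80, 100]
    range_b: [80, 100]
    range_c: [0, 5]
    proposed: true
  - icpc: D82
    label: "Teeth / gum disease"
    min_age: 18
    max_age: ~
    sex: ~
    recommended: ["J01CA04"]
    range_a: [0, 30]
    range_b: [80, 100]
    range_c: [0, 5]
    proposed: true
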