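# Drug-gene actionability rules (CPIC/DPWG/FDA-derived).
# category 2: genotype would benefit from guided drug/dose selection.
# category 3: genotype associated with serious / life-threatening adverse
#             response to the listed drugs.
# trigger: phenotype classes that fire the rule. Specialty tags come from
# the closed vocabulary {cardiology, psychiatry, infectious_diseases,
# neurology, gastroenterology, transplant, pain, oncology}.
rules:
  - gene: HLA-B
    trigger: [carrier]
    category: 3
    drugs: [abacavir]
    specialties: [infectious_diseases]
    source: CPIC
  - gene: HLA-A
    trigger: [carrier]
    category: 3
    drugs: [carbamazepine]
    specialties: [neurology, psychiatry, pain]
    source: CPIC
  - gene: TPMT
    trigger: [intermediate, poor]
    category: 3
    drugs: [azathioprine, mercaptopurine, thioguanine]
    specialties: [gastroenterology, oncology]
    source: CPIC
  - gene: DPYD
    trigger: [intermediate, poor]
    category: 3
    drugs: [capecitabine, fluorouracil, tegafur]
    specialties: [oncology]
    source: CPIC
  - gene: CYP2D6
    trigger: [ultrarapid]
    category: 3
    drugs: [codeine, tramadol, oxycodone]
    specialties: [pain]
    source: CPIC
  - gene: CYP2D6
    trigger: [poor, intermediate]
    category: 2
    drugs: [codeine, tramadol, amitriptyline, nortriptyline, paroxetine,
            venlafaxine, aripiprazole, atomoxetine, flecainide,
            propafenone, tamoxifen]
    specialties: [pain, psychiatry, cardiology, oncology]
    source: CPIC
  - gene: CYP2C19
    trigger: [poor, intermediate, ultrarapid]
    category: 2
    drugs: [clopidogrel, citalopram, escitalopram, sertraline,
            amitriptyline, clomipramine, omeprazole, esomeprazole,
            lansoprazole, pantoprazole]
    specialties: [cardiology, psychiatry, gastroenterology, neurology]
    source: CPIC
  - gene: CYP2C9
    trigger: [poor, intermediate]
    category: 2
    drugs: [warfarin]
    specialties: [cardiology, neurology]
    source: CPIC
  - gene: VKORC1
    trigger: [decreased_function]
    category: 2
    drugs: [warfarin]
    specialties: [cardiology, neurology]
    source: CPIC
  - gene: SLCO1B1
    trigger: [decreased_function]
    category: 2
    drugs: [simvastatin]
    specialties: [cardiology]
    source: CPIC
  - gene: CYP3A5
    trigger: [extensive, intermediate]
    category: 2
    drugs: [tacrolimus]
    specialties: [transplant]
    source: CPIC
  - gene: IFNL3
    trigger: [decreased_function]
    category: 2
    drugs: [peginterferon alfa-2a, peginterferon alfa-2b, ribavirin,
            boceprevir, telaprevir]
    specialties: [infectious_diseases]
    source: CPIC
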