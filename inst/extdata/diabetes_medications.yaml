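# 17 generic diabetes medications with common Australian brand aliases.
# Illustrative configuration for the prescription route of the new-onset
# diabetes phenotype.
- {generic: metformin,      brands: [Diabex, Diaformin, Glucophage]}
- {generic: gliclazide,     brands: [Diamicron, Glyade]}
- {generic: glibenclamide,  brands: [Daonil, Glimel]}
- {generic: glimepiride,    brands: [Amaryl, Dimirel]}
- {generic: glipizide,      brands: [Minidiab]}
- {generic: sitagliptin,    brands: [Januvia]}
- {generic: vildagliptin,   brands: [Galvus]}
- {generic: saxagliptin,    brands: [Onglyza]}
- {generic: linagliptin,    brands: [Trajenta]}
- {generic: alogliptin,     brands: [Nesina]}
- {generic: empagliflozin,  brands: [Jardiance]}
- {generic: dapagliflozin,  brands: [Forxiga]}
- {generic: ertugliflozin,  brands: [Steglatro]}
- {generic: exenatide,      brands: [Byetta, Bydureon]}
- {generic: dulaglutide,    brands: [Trulicity]}
- {generic: semaglutide,    brands: [Ozempic, Rybelsus]}
- {generic: pioglitazone,   brands: [Actos]}
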