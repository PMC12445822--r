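format-version: 1.2
data-version: synthetic/2026-01-01
ontology: go-synthetic

[Term]
id: GO:0000001
name: biological_process root
namespace: biological_process

[Term]
id: GO:0000002
name: metabolic process
namespace: biological_process
is_a: GO:0000001 ! biological_process root

[Term]
id: GO:0000003
name: carbohydrate metabolic process
namespace: biological_process
is_a: GO:0000002 ! metabolic process

[Term]
id: GO:0000004
name: glycolytic process
namespace: biological_process
is_a: GO:0000003 ! carbohydrate metabolic process
is_a: GO:0000008 ! ATP generation

[Term]
id: GO:0000005
name: tricarboxylic acid cycle
namespace: biological_process
is_a: GO:0000002 ! metabolic process
is_a: GO:0000008 ! ATP generation

[Term]
id: GO:0000006
name: oxidation-reduction process
namespace: biological_process
is_a: GO:0000002 ! metabolic process

[Term]
id: GO:0000007
name: superoxide metabolic process
namespace: biological_process
is_a: GO:0000006 ! oxidation-reduction process

[Term]
id: GO:0000008
name: ATP generation
namespace: biological_process
is_a: GO:0000002 ! metabolic process

[Term]
id: GO:0000009
name: protein folding
namespace: biological_process
is_a: GO:0000001 ! biological_process root

[Term]
id: GO:0000010
name: chaperone-mediated protein folding
namespace: biological_process
is_a: GO:0000009 ! protein folding

[Term]
id: GO:0000011
name: response to stress
namespace: biological_process
is_a: GO:0000001 ! biological_process root

[Term]
id: GO:0000012
name: response to oxidative stress
namespace: biological_process
is_a: GO:0000011 ! response to stress

[Term]
id: GO:0000013
name: response to heat
namespace: biological_process
is_a: GO:0000011 ! response to stress

[Term]
id: GO:0000014
name: translation
namespace: biological_process
is_a: GO:0000002 ! metabolic process

[Term]
id: GO:0000015
name: obsolete sugar burning
namespace: biological_process
is_obsolete: true

[Term]
id: GO:0000101
name: cellular_component root
namespace: cellular_component

[Term]
id: GO:0000102
name: intracellular anatomical structure
namespace: cellular_component
is_a: GO:0000101 ! cellular_component root

[Term]
id: GO:0000103
name: cytoplasm
namespace: cellular_component
is_a: GO:0000102 ! intracellular anatomical structure

[Term]
id: GO:0000104
name: mitochondrion
namespace: cellular_component
is_a: GO:0000103 ! cytoplasm

[Term]
id: GO:0000105
name: mitochondrial matrix
namespace: cellular_component
is_a: GO:0000104 ! mitochondrion

[Term]
id: GO:0000106
name: cytosol
namespace: cellular_component
is_a: GO:0000103 ! cytoplasm

[Term]
id: GO:0000107
name: ribosome
namespace: cellular_component
is_a: GO:0000102 ! intracellular anatomical structure

[Term]
id: GO:0000201
name: molecular_function root
namespace: molecular_function

[Term]
id: GO:0000202
name: catalytic activity
namespace: molecular_function
is_a: GO:0000201 ! molecular_function root

[Term]
id: GO:0000203
name: lyase activity
namespace: molecular_function
is_a: GO:0000202 ! catalytic activity

[Term]
id: GO:0000204
name: fructose-bisphosphate aldolase activity
namespace: molecular_function
is_a: GO:0000203 ! lyase activity

[Term]
id: GO:0000205
name: oxidoreductase activity
namespace: molecular_function
is_a: GO:0000202 ! catalytic activity

[Term]
id: GO:0000206
name: superoxide dismutase activity
namespace: molecular_function
is_a: GO:0000205 ! oxidoreductase activity

[Term]
id: GO:0000207
name: ATP binding
namespace: molecular_function
is_a: GO:0000201 ! molecular_function root

[Term]
id: GO:0000208
name: unfolded protein binding
namespace: molecular_function
is_a: GO:0000201 ! molecular_function root
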