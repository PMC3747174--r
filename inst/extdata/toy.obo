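format-version: 1.4
ontology: toy

[Term]
id: GO:0000001
name: toy root
namespace: toy_process

[Term]
id: GO:0000002
name: branch one
namespace: toy_process
is_a: GO:0000001 ! toy root

[Term]
id: GO:0000003
name: branch two
namespace: toy_process
is_a: GO:0000001 ! toy root

[Term]
id: GO:0000004
name: leaf under branch one
namespace: toy_process
alt_id: GO:0000044
is_a: GO:0000002 ! branch one

[Term]
id: GO:0000005
name: diamond leaf
namespace: toy_process
is_a: GO:0000001 ! reachable at depth 2 ...
is_a: GO:0000004 ! ... and at depth 4

[Term]
id: GO:0000006
name: partonomy leaf
namespace: toy_process
relationship: part_of GO:0000003 ! linked only by part_of

[Term]
id: GO:0000007
name: retired term
namespace: toy_process
is_obsolete: true
is_a: GO:0000002

[Typedef]
id: part_of
name: part of
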