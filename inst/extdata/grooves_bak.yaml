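# Default BAK groove definitions in the override format accepted by
# `read_grooves_yaml()` / the pipeline `map.grooves` key (author/PDB 2IMS
# residue numbering).  Edit or extend to redefine grooves.
canonical: [82, 83, 85, 89, 90, 91, 93, 94, 95, 96, 97, 98, 99, 108,
            113, 114, 118, 126, 130, 131, 132, 133, 134]
noncanonical: [96, 98, 99, 113, 114, 118, 157, 161, 162, 163, 164, 165,
               166, 168]
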