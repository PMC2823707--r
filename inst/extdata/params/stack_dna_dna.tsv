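# Nearest-neighbor stack parameters, DNA/DNA (unified oligonucleotide set).
# Grammar: one stack per line: <dinucleotide 5'->3'> <dH kcal/mol> <dS cal/(K*mol)>.
# The dinucleotide names positions (i, i+1) of one strand; the paired strand
# is its Watson-Crick complement read antiparallel, so the table is symmetric
# under reverse-complement of the key (AA == TT, CA == TG, ...).
# The special key 'init' is the duplex initiation term (helix initiation for
# the melting-temperature equation is carried separately by the A factor of
# the hybridization conditions, hence 0 here).
# reference: SantaLucia unified DNA nearest-neighbor parameters
AA	-7.9	-22.2
AT	-7.2	-20.4
AC	-8.4	-22.4
AG	-7.8	-21.0
TA	-7.2	-21.3
TT	-7.9	-22.2
TC	-8.2	-22.2
TG	-8.5	-22.7
CA	-8.5	-22.7
CT	-7.8	-21.0
CC	-8.0	-19.9
CG	-10.6	-27.2
GA	-8.2	-22.2
GT	-8.4	-22.4
GC	-9.8	-24.4
GG	-8.0	-19.9
init	0.0	0.0
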