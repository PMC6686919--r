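#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
t2                   -             25 synthetic_domain     -             25   3.3e-24   72.6  11.7   1   1   2.3e-24   3.4e-24   72.5  11.7     1    25     1    25     1    25 0.98 -
t1                   -             75 synthetic_domain     -             25     4e-23   69.1  11.7   1   1   4.8e-23   7.3e-23   68.2  11.7     1    25    31    55    31    55 0.98 -
#
# Program:         hmmsearch
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SEARCH
# Query file:      /root/pkg/scratch/synthetic_domain.hmm
# Target file:     /root/pkg/scratch/targets.fasta
# Option settings: hmmsearch --domtblout /root/pkg/scratch/dom.tbl -E 1000 /root/pkg/scratch/synthetic_domain.hmm /root/pkg/scratch/targets.fasta 
# Current dir:     /root/pkg
# Date:            Mon Sep 21 13:11:37 2026
# [ok]
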