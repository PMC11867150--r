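
DNA parsimony algorithm, version 3.697

     4 sequences,  12 sites

                                            +--seqA
     +--------------------------------------2
  1--+                                      +--seqB
     |
     +--seqC
     +--seqD

requires a total of      4.000

From    To     Any Steps?    State at upper node
                             ( . means same as in the node below it on tree)

          1                AACGTA CCGGTT
   1      2         yes    .G.... ......
   2   seqA         no     ...... ......
   2   seqB         maybe  ....C. ......
   1   seqC         no     ...... ...A..
   1   seqD         no     ..T... ......


     +--seqA
  1--+            +--seqB
     +------------2--seqC
                  +--seqD

requires a total of      5.000

From    To     Any Steps?    State at upper node
                             ( . means same as in the node below it on tree)

          1                AGCGTA
   1   seqA         no     ......
   1      2         yes    .AN...
   2   seqB         no     AGCGCA
   2   seqC         maybe  AACGTA
   2   seqD         no     AATGTA

From    To     Any Steps?    State at upper node
                             ( . means same as in the node below it on tree)

          1                CCGGTT
   1   seqA         no     ......
   1      2         yes    ......
   2   seqB         no     CCGGTT
   2   seqC         maybe  CCGATT
   2   seqD         no     CCGGTT

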