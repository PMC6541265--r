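study_id,available_data,measure,intervention,n_t,n_c,n_total,r
Bedard.2003.1,prepost-msds,BDI-II,Mindfulness,10,3,13,0.24
Cheavens.2006.1,prepost-msds,CES-D,Hope therapy,16,16,32,0.23
Davis.2004.1,post-msds,SZD,Life Review therapy,7,7,14,0.81
Fava.1998.1,prepost-msds,CID-DEP,Well-being therapy,10,10,20,0.53
Fava.1998.1,prepost-msds,SQ-DEP,Well-being therapy,10,10,20,0.04
Fava.2005.1,prepost-msds,CID-DEP,Well-being therapy,8,8,16,0.28
Fava.2005.1,prepost-msds,SQ-DEP,Well-being therapy,8,8,16,0.22
Fordyce.1983.4,post-msds,DAC,Fundamentals,64,39,103,0.14
Fordyce.1983.6,prepost-msds,DAC,Fundamentals,14,13,27,0.05
Fordyce.1983.6,prepost-msds,DAC,Fundamentals—personality,10,13,23,0
Fordyce.1983.6,prepost-msds,DAC,Fundamentals—attitudes,12,13,25,0.18
Fordyce.1983.6,prepost-msds,DAC,Fundamentals—lifestyle,8,13,21,0.26
Freedman.1996.1,prepost-msds,BDI,Forgiveness,6,6,12,0.52
Grossman.2007.1,prepost-msds,HADS-D,Mindfulness,39,13,52,0.21
Lichter.1980.2,prepost-msds,BDI,Positive feeling statements,25,23,48,0.2
Lin.2004.1,prepost-msds,BDI-II,Forgiveness therapy,14,14,28,0.66
Reed.2006.1,prepost-msds,BDI-II,Forgiveness therapy,10,10,20,0.61
Ruini.2006.1,prepost-msds,SQ-DEP,Well-being therapy,57,54,111,-0.12
Seligman.2004.1,post-cohend,CES-D,Unspecified,102,83,185,-0.15
Seligman.2005.1,prepost-msds,CES-D,Gratitude visit,80,70,150,0.16
Seligman.2005.1,prepost-msds,CES-D,Three good things,59,70,129,0.1
Seligman.2005.1,prepost-msds,CES-D,You at your best,68,70,138,0.1
Seligman.2005.1,prepost-msds,CES-D,Signature strengths,66,70,136,0.07
Seligman.2005.1,prepost-msds,CES-D,Identifying signature strengths,68,70,138,0.03
Seligman.2006.1,prepost-msds,BDI-II,Positive psychotherapy,14,20,34,0.22
Seligman.2006.2,prepost-msds,ZSRS,Positive psychotherapy,11,9,20,0.47
Seligman.2006.2,post-msds,HRSD,Positive psychotherapy,11,9,20,0.59
Smith.1995.1,prepost-difmsds,BDI,Personal happiness,17,12,29,0.39
Smith.1995.1,prepost-difmsds,BDI,Personal happiness w/ meditation,7,12,19,0.6
Surawy.2005.1,prepost-msds,HADS-D,Mindfulness,9,8,17,0.19
Zautra.2008.1a,prepost-msds,DEPS-NS,Mindfulness,41,30,71,-0.03
Zautra.2008.1b,prepost-msds,DEPS-NS,Mindfulness,6,14,20,0.31
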