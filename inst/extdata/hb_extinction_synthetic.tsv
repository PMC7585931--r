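# Synthetic oxy/deoxy-hemoglobin molar extinction compilation (base-10),
# units cm^-1 M^-1; generated by scripts/make_extinction_table.R.
wavelength_nm	eps_hbo	eps_hbr
450	62816	75000
451	60471.5	73627.3
452	58239	72215.7
453	56115.1	70769.1
454	54096.4	69291.5
455	52179.4	67787
456	50360.7	66259.5
457	48636.9	64713.1
458	47004.5	63151.7
459	45460	61579.3
460	44000	60000
461	42621	58418
462	41319.2	56838.9
463	40090.5	55268.3
464	38931.1	53712.1
465	37837.1	52176
466	36804.4	50665.9
467	35829.2	49187.4
468	34907.5	47746.4
469	34035.4	46348.7
470	33209	45000
471	32424.7	43704.6
472	31680.6	42460.9
473	30975.3	41265.8
474	30307.3	40116.2
475	29675.1	39009
476	29077.3	37941
477	28512.3	36909.2
478	27978.8	35910.5
479	27475.2	34941.8
480	27000	34000
481	26551.7	33082.6
482	26128.3	32189.5
483	25727.8	31321.5
484	25348	30479.2
485	24986.8	29663.2
486	24642.2	28874.1
487	24312.1	28112.6
488	23994.5	27379.4
489	23687.1	26674.9
490	23388	26000
491	23095.6	25355.2
492	22810.5	24741
493	22533.9	24158.1
494	22266.9	23607
495	22010.8	23088.3
496	21766.5	22602.5
497	21535.4	22150.2
498	21318.4	21732
499	21116.9	21348.4
500	20932	21000
501	20764.6	20687.3
502	20614.7	20410.4
503	20482.3	20169.5
504	20367.3	19964.7
505	20269.5	19796.1
506	20188.9	19663.8
507	20125.2	19567.9
508	20078.4	19508.6
509	20048.4	19485.9
510	20035	19500
511	20041.3	19551.3
512	20083.4	19641.4
513	20180.2	19772.4
514	20350.9	19946.3
515	20614.8	20164.9
516	20990.8	20430.4
517	21498.2	20744.6
518	22156.1	21109.7
519	22983.7	21527.5
520	24000	22000
521	25215.4	22529.1
522	26605.1	23115.9
523	28135.4	23761.3
524	29772.6	24466.3
525	31483.1	25231.8
526	33233.1	26058.7
527	34989.1	26948.1
528	36717.3	27900.8
529	38384.2	28917.8
530	39956	30000
531	41407	31145.8
532	42743.4	32343
533	43979.3	33576.9
534	45128.8	34832.7
535	46205.9	36095.5
536	47224.8	37350.8
537	48199.6	38583.6
538	49144.3	39779.3
539	50073.1	40923
540	51000	42000
541	51910.4	43000.6
542	52674.3	43935.3
543	53133	44819.7
544	53127.9	45669.4
545	52500	46500
546	51159	47323.7
547	49287.6	48139.7
548	47136.7	48943.9
549	44957.2	49732
550	43000	50500
551	41441.4	51239.8
552	40159.1	51928.1
553	38956.1	52537.7
554	37635.4	53041.4
555	36000	53412
556	33936	53627.7
557	31662.2	53688.8
558	29480.4	53600.8
559	27692.4	53369.3
560	26600	53000
561	26424	52504.2
562	27060.7	51916.3
563	28325.5	51276.2
564	30033.5	50624.1
565	32000	50000
566	34078.4	49430.4
567	36274.1	48887.1
568	38630.6	48328.8
569	41191.4	47713.6
570	44000	47000
571	47041.7	46158.4
572	50068.6	45207.1
573	52774.7	44176.7
574	54853.9	43097.5
575	56000	42000
576	55994.9	40912.1
577	54971.5	39852.3
578	53150.6	38836.4
579	50753.2	37880.3
580	48000	37000
581	45074.9	36201.1
582	42013.5	35447.7
583	38814.8	34693.8
584	35477.4	33893.3
585	32000	33000
586	28401.7	31979.6
587	24782.4	30844.9
588	21262.2	29620.4
589	17961.4	28330.5
590	15000	27000
591	12471	25651.1
592	10358	24297.4
593	8617.4	22950.5
594	7205.7	21621.9
595	6079.2	20323.1
596	5194.5	19065.4
597	4507.7	17860.5
598	3975.5	16719.8
599	3554.1	15654.8
600	3200	14677
601	2876.8	13794.7
602	2577.1	13003.1
603	2300.7	12294.6
604	2047.3	11661.3
605	1816.8	11095.2
606	1609	10588.6
607	1423.6	10133.6
608	1260.4	9722.4
609	1119.3	9347.2
610	1000	9000
611	902	8674.2
612	823.2	8367.8
613	761.2	8079.7
614	713.8	7809.1
615	678.4	7555.1
616	652.8	7316.6
617	634.5	7092.8
618	621.2	6882.7
619	610.5	6685.4
620	600	6500
621	587.8	6325.6
622	573.8	6161.5
623	558.6	6007.2
624	542.4	5862
625	525.7	5725.4
626	509	5596.8
627	492.7	5475.5
628	477.1	5361
629	462.7	5252.7
630	450	5150
631	439.2	5052.3
632	430.3	4959.3
633	422.9	4870.7
634	417.1	4786.3
635	412.4	4705.7
636	408.7	4628.6
637	405.9	4554.8
638	403.6	4483.9
639	401.7	4415.8
640	400	4350
641	398.3	4286.3
642	396.5	4224.4
643	394.4	4163.9
644	392.2	4104.4
645	389.5	4045.6
646	386.4	3987.2
647	382.8	3928.8
648	378.6	3870
649	373.7	3810.5
650	368	3750
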