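>PolA_1|PolA
MVLRLTYKGHRANEPLYLVTEGHCITRVGSRGGVSALDPLYSPIDDSLNVTREYLILRADRALARDIKALHHPETPLSLE
LGLQALYEDRYALERSSLD
>PolA_2|PolA
MVARLTIKNAGVNHSLILIMEGKPISAGLLWGGVVADRPSVRGITDSLNTHREISVLPHCRTPVRHRKRLDIGLTGFSIE
VGQLALPEDHYALERIKSV
>PolB_1|PolB
MLGLYLAPVSLYLGFRKKATGPSRFCRALILTSNGRLAIEASRFLSTRQVLLRIYGATGHLPDCAPERTRPIPRPASVAC
VCNLLIRVRPSVMQWTSTT
>PolB_2|PolB
MIQCCCPPVSLTAGTGRKATRSGSFTRDLTLPYKYRHLVSAQPRLATGQQYSRIWGATTGHVDCRAEPSRCIARQAAVAS
VIGLRCRVSLTTMFWTSSV
>PolC_1|PolC
MCSGATQHEWRWHVSYSLLTSPLGSPTVPSKVKYLRVPLQSQRLSVEFVGRGVVMQRPDGTSLTNFIQSILMLRQTHNCQ
LRTSGRSKGDTLQAPWHNA
>PolC_2|PolC
MCRFATLHAARVASWLSKIAHPLGSPPVPSKVKRLPPPGASSNSSRELQGRPLKYQVPNGETSTWTYQDILMLPQNHPFQ
LRILPQSAMRTLLAVRTNY
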