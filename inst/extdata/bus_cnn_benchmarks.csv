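subset,mode,model,condition,global_accuracy,mean_iou,mean_bf
benign,batch,FCN-AlexNet,before,90.62,49.11,44.68
benign,batch,U-Net,before,91.08,49.09,44.93
benign,batch,SegNet-VGG16,before,90.99,49.13,45.31
benign,batch,SegNet-VGG19,before,90.88,49.13,45.26
benign,batch,DeepLabV3+-ResNet18,before,90.54,48.87,45.14
benign,batch,DeepLabV3+-ResNet50,before,90.47,48.80,45.10
benign,batch,DeepLabV3+-MobileNet-V2,before,90.94,48.99,45.13
benign,batch,DeepLabV3+-Xception,before,90.81,49.08,45.10
benign,batch,FCN-AlexNet,after,97.22,78.60,63.78
benign,batch,U-Net,after,97.40,78.65,77.22
benign,batch,SegNet-VGG16,after,98.14,83.77,82.31
benign,batch,SegNet-VGG19,after,98.16,84.00,82.66
benign,batch,DeepLabV3+-ResNet18,after,98.01,83.84,81.91
benign,batch,DeepLabV3+-ResNet50,after,98.38,85.70,83.49
benign,batch,DeepLabV3+-MobileNet-V2,after,97.78,81.27,80.66
benign,batch,DeepLabV3+-Xception,after,98.11,83.99,82.01
malignant,batch,FCN-AlexNet,before,81.34,50.08,40.43
malignant,batch,U-Net,before,83.09,50.58,40.91
malignant,batch,SegNet-VGG16,before,81.65,50.45,39.53
malignant,batch,SegNet-VGG19,before,81.94,50.72,40.12
malignant,batch,DeepLabV3+-ResNet18,before,80.83,49.97,40.18
malignant,batch,DeepLabV3+-ResNet50,before,80.07,49.34,40.07
malignant,batch,DeepLabV3+-MobileNet-V2,before,81.71,50.31,40.47
malignant,batch,DeepLabV3+-Xception,before,80.34,50.03,39.63
malignant,batch,FCN-AlexNet,after,92.06,72.21,50.89
malignant,batch,U-Net,after,91.74,69.39,54.50
malignant,batch,SegNet-VGG16,after,93.53,76.91,57.42
malignant,batch,SegNet-VGG19,after,93.53,76.57,58.80
malignant,batch,DeepLabV3+-ResNet18,after,93.34,77.22,59.33
malignant,batch,DeepLabV3+-ResNet50,after,93.91,77.78,60.21
malignant,batch,DeepLabV3+-MobileNet-V2,after,92.80,73.81,55.93
malignant,batch,DeepLabV3+-Xception,after,93.02,75.39,58.06
benign,one_by_one,FCN-AlexNet,before,98.08,84.03,68.08
benign,one_by_one,U-Net,before,98.03,82.92,83.15
benign,one_by_one,SegNet-VGG16,before,98.50,86.60,85.57
benign,one_by_one,SegNet-VGG19,before,98.66,88.06,86.19
benign,one_by_one,DeepLabV3+-ResNet18,before,98.76,89.13,86.40
benign,one_by_one,DeepLabV3+-ResNet50,before,98.76,89.24,86.33
benign,one_by_one,DeepLabV3+-MobileNet-V2,before,98.57,87.24,86.15
benign,one_by_one,DeepLabV3+-Xception,before,98.51,86.98,85.75
benign,one_by_one,FCN-AlexNet,after,97.22,78.60,63.78
benign,one_by_one,U-Net,after,97.40,78.65,77.22
benign,one_by_one,SegNet-VGG16,after,98.14,83.75,82.30
benign,one_by_one,SegNet-VGG19,after,98.16,83.97,82.66
benign,one_by_one,DeepLabV3+-ResNet18,after,98.01,83.84,81.91
benign,one_by_one,DeepLabV3+-ResNet50,after,98.38,85.70,83.49
benign,one_by_one,DeepLabV3+-MobileNet-V2,after,97.78,81.27,80.66
benign,one_by_one,DeepLabV3+-Xception,after,98.11,83.99,82.01
malignant,one_by_one,FCN-AlexNet,before,92.77,75.34,51.83
malignant,one_by_one,U-Net,before,92.64,73.03,56.29
malignant,one_by_one,SegNet-VGG16,before,94.54,80.40,59.67
malignant,one_by_one,SegNet-VGG19,before,94.68,80.69,60.49
malignant,one_by_one,DeepLabV3+-ResNet18,before,94.82,81.83,61.88
malignant,one_by_one,DeepLabV3+-ResNet50,before,94.62,81.58,60.03
malignant,one_by_one,DeepLabV3+-MobileNet-V2,before,93.82,78.09,60.17
malignant,one_by_one,DeepLabV3+-Xception,before,93.25,77.80,59.93
malignant,one_by_one,FCN-AlexNet,after,92.06,72.21,50.89
malignant,one_by_one,U-Net,after,91.74,69.39,54.50
malignant,one_by_one,SegNet-VGG16,after,93.51,76.86,57.41
malignant,one_by_one,SegNet-VGG19,after,93.52,76.56,58.83
malignant,one_by_one,DeepLabV3+-ResNet18,after,93.34,77.22,59.33
malignant,one_by_one,DeepLabV3+-ResNet50,after,93.91,77.78,60.21
malignant,one_by_one,DeepLabV3+-MobileNet-V2,after,92.80,73.81,55.93
malignant,one_by_one,DeepLabV3+-Xception,after,93.02,75.39,58.05
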